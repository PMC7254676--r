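# Ground-truth generator: planted networks, rasters, presets, rendering.

test_that("p_intra = 1 with one module gives the complete digraph", {
  net <- make_ground_truth_network(4, 1, p_intra = 1, p_inter = 0, seed = 3)
  expect_equal(sum(net$adjacency), 12L)
  expect_true(all(diag(net$adjacency) == 0L))
})

test_that("realized intra-module density matches its binomial expectation", {
  net <- make_ground_truth_network(100, 4, 0.3, 0.01, seed = 1)
  same <- outer(net$modules, net$modules, "==")
  diag(same) <- FALSE
  n_pairs <- sum(same)                      # 4 * 25 * 24 ordered pairs
  k <- sum(net$adjacency[same])
  expect_equal(n_pairs, 2400L)
  sdev <- sqrt(n_pairs * 0.3 * 0.7)
  expect_lt(abs(k - n_pairs * 0.3), 3 * sdev)
  inter_pairs <- sum(!same) - 100
  k_inter <- sum(net$adjacency[!same & !diag(100)])
  expect_lt(abs(k_inter - inter_pairs * 0.01),
            3 * sqrt(inter_pairs * 0.01 * 0.99))
})

test_that("p_inter = 0 disconnects the modules", {
  net <- make_ground_truth_network(60, 3, 0.4, 0, seed = 2)
  cross <- outer(net$modules, net$modules, "!=")
  expect_equal(sum(net$adjacency[cross]), 0L)
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "directed")
  comp <- igraph::components(g, mode = "weak")$membership
  # no weak component spans two modules
  expect_true(all(tapply(net$modules, comp, function(m)
    length(unique(m))) == 1L))
})

test_that("more modules than neurons is a parameter error", {
  expect_error(make_ground_truth_network(3, 5, 0.5, 0.1), "exceed")
})

test_that("identical seed and params give a bitwise-identical culture", {
  p <- tiny_params()
  a <- simulate_raster(p, seed = 42)
  b <- simulate_raster(p, seed = 42)
  expect_identical(a$raster$events, b$raster$events)
  expect_identical(a$roles, b$roles)
  expect_identical(a$schedule$onset, b$schedule$onset)
  c2 <- simulate_raster(p, seed = 43)
  expect_false(identical(a$raster$events, c2$raster$events))
})

test_that("raster spike count decomposes into burst + background spikes", {
  cu <- simulate_raster(tiny_params(), seed = 5, bursty = TRUE)
  expect_equal(nrow(cu$raster$events),
               cu$counts$burst + cu$counts$independent + cu$counts$overflow)
  # participants subset of active neurons; scheduled bursts large enough
  for (pp in cu$schedule$participants)
    expect_true(all(pp %in% cu$active_ids))
})

test_that("zero rates give an empty raster", {
  p <- tiny_params(independent_rate = 0, independent_rate_nonbursty = 0,
                   bursty_fraction = 0)
  cu <- simulate_raster(p, seed = 1)
  expect_equal(nrow(cu$raster$events), 0L)
})

test_that("background spike totals follow the Poisson expectation", {
  # 10 active neurons at 0.5 spikes/s for 600 s, no bursts: ~3000 spikes
  p <- generator_params(n_rois = 12, frac_active = 10 / 12, frac_glia = 0,
                        duration = 600, frame_rate = 20,
                        bursty_fraction = 0, independent_rate_nonbursty = 0.5,
                        independent_rate = 0.5, n_modules = 1)
  cu <- simulate_raster(p, seed = 11)
  expect_lt(abs(nrow(cu$raster$events) - 3000), 3 * sqrt(3000))
})

test_that("generated burst schedules realize the preset inter-burst interval", {
  p <- get_preset("WT-STR", n_rois = 150)
  ibis <- unlist(lapply(1:10, function(s) {
    cu <- simulate_raster(p, seed = 100 + s, bursty = TRUE)
    diff(cu$schedule$onset)
  }))
  expect_lt(abs(mean(ibis) - p$mean_ibi) / p$mean_ibi, 0.10)
})

test_that("presets carry the published group statistics and reject unknown names", {
  expect_equal(get_preset("WT-STR")$frac_active, 0.14)
  expect_equal(get_preset("HD-STR")$mean_ibi, 24)
  expect_equal(get_preset("HD-STR")$frac_active, 0.08)
  expect_equal(get_preset("WT-STR")$mean_ibi, 17)
  expect_error(get_preset("WT-HIP"), "unknown preset")
  # NMDA-like: raised background drive, no coherent bursts
  nmda <- get_preset("NMDA-like")
  expect_equal(nmda$bursty_fraction, 0)
  expect_gt(nmda$independent_rate, get_preset("WT-STR")$independent_rate)
  expect_gt(nmda$frac_active, get_preset("WT-STR")$frac_active)
})

test_that("stratified batches hit the bursty fraction exactly", {
  p <- tiny_params(bursty_fraction = 0.6)
  cus <- simulate_batch(p, 10, seed = 3)
  expect_equal(sum(vapply(cus, `[[`, TRUE, "bursty")), 6L)
})

test_that("a rendered spike decays as the calcium kernel", {
  p <- tiny_params(noise_sd = 0, drift_amplitude = 0, bursty_fraction = 0,
                   independent_rate = 0, frac_glia = 0)
  cu <- simulate_raster(p, seed = 1)
  i <- cu$active_ids[1]
  cu$raster <- spike_raster(data.frame(neuron = i, frame = 100L),
                            p$n_rois, 1200L, 20)
  tr <- render_traces(cu, noise = FALSE, drift = FALSE)
  fr <- 20; tau <- p$kernel_decay
  for (k in c(0, 1, 5, 40))
    expect_equal(tr$clean[i, 100 + k],
                 p$kernel_amplitude * exp(-k / (tau * fr)), tolerance = 1e-12)
  expect_equal(tr$clean[i, 99], 0)
})

test_that("two spikes one frame apart superpose linearly", {
  p <- tiny_params(noise_sd = 0, drift_amplitude = 0, frac_glia = 0)
  cu <- simulate_raster(p, seed = 1, bursty = FALSE)
  i <- cu$active_ids[1]
  cu$raster <- spike_raster(data.frame(neuron = i, frame = c(50L, 51L)),
                            p$n_rois, 600L, 20)
  tr <- render_traces(cu, noise = FALSE, drift = FALSE)
  a <- p$kernel_amplitude
  expect_equal(tr$clean[i, 51], a * (1 + exp(-1 / (3 * 20))),
               tolerance = 1e-12)
})

test_that("noiseless rendering followed by peeling returns the raster exactly", {
  p <- tiny_params(noise_sd = 0, drift_amplitude = 0)
  cu <- simulate_raster(p, seed = 9, bursty = TRUE)
  tr <- render_traces(cu, noise = FALSE, drift = FALSE)
  kern <- calcium_kernel(p$kernel_amplitude, p$kernel_decay)
  for (i in cu$active_ids) {
    rec <- reconstruct_spikes(tr$clean[i, ], kern, p$frame_rate)
    truth <- sort(cu$raster$events$frame[cu$raster$events$neuron == i])
    expect_identical(as.integer(rec), as.integer(truth))
  }
})

test_that("generator parameter validation rejects bad inputs", {
  expect_error(generator_params(frac_active = 1.2), "fraction")
  expect_error(generator_params(duration = 10.37, frame_rate = 3),
               "integer frame count")
  expect_error(generator_params(spikes_per_burst_neuron = 0), ">= 1")
  p <- tiny_params()
  net <- make_ground_truth_network(5, 1, 0.5, 0)
  expect_error(simulate_raster(p, network = net, seed = 1), "active neurons")
})
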