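# Network-burst detection (Schmitt trigger), activity summary, independent
# spikes.

# literal per-sample state machine, kept deliberately naive as the oracle
schmitt_oracle <- function(sig, hi, lo) {
  out <- NULL
  on <- FALSE
  open <- NA
  for (t in seq_along(sig)) {
    if (!on && sig[t] >= hi) {
      on <- TRUE; open <- t
    } else if (on && sig[t] < lo) {
      out <- rbind(out, c(open, t - 1L))
      on <- FALSE
    }
  }
  if (on) out <- rbind(out, c(open, length(sig)))
  if (is.null(out)) out <- matrix(integer(0), 0, 2)
  dimnames(out) <- list(NULL, c("open", "close"))
  out
}

raster_from_events <- function(neuron, frame, n_neurons, n_frames, fr = 20) {
  spike_raster(data.frame(neuron = neuron, frame = frame), n_neurons,
               n_frames, fr)
}

test_that("Schmitt segmentation equals the state-machine oracle on 1000 random signals", {
  set.seed(99)
  for (i in 1:1000) {
    sig <- rpois(120, lambda = runif(1, 1, 9))
    hi <- sample(4:9, 1)
    lo <- sample.int(hi, 1) - 1L
    got <- schmitt_segments(sig, hi, lo)
    ref <- schmitt_oracle(sig, hi, lo)
    expect_identical(got, ref)
  }
})

test_that("an empty raster yields no bursts", {
  r <- spike_raster(NULL, 50, 1000, 20)
  b <- detect_network_bursts(r, active_ids = 1:50)
  expect_equal(nrow(b), 0)
})

test_that("a single synchronous volley is one burst with its participants", {
  # 15 distinct neurons of 100 spike within one 1 s window, silence elsewhere
  fr <- 20
  frames <- 500L + seq(0L, 14L)
  r <- raster_from_events(1:15, frames, 100, 2000, fr)
  b <- detect_network_bursts(r, active_ids = 1:100)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_participants, 15)
  expect_setequal(b$participants[[1]], 1:15)
  # oracle cross-check on the constructed activity signal
  sig <- calnet:::activity_signal(r, fr)
  ref <- schmitt_oracle(sig, 10, 5)
  expect_equal(nrow(ref), 1)
})

test_that("bursts less than half a second apart are merged", {
  fr <- 20
  # two synchronous 12-neuron volleys whose trigger segments close and
  # reopen 0.45 s apart -> merged into one burst
  b1 <- data.frame(neuron = 1:12, frame = 300L)
  b2 <- data.frame(neuron = 13:24, frame = 328L)
  r <- spike_raster(rbind(b1, b2), 100, 2000, fr)
  b <- detect_network_bursts(r, active_ids = 1:100)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_participants, 24)
  # the same two volleys with a 1 s trigger gap stay separate
  b2far <- data.frame(neuron = 13:24, frame = 340L)
  rfar <- spike_raster(rbind(b1, b2far), 100, 2000, fr)
  bf <- detect_network_bursts(rfar, active_ids = 1:100)
  expect_equal(nrow(bf), 2)
})

test_that("bursts with fewer than 10 participants are discarded", {
  r <- raster_from_events(1:9, 500L + (0:8), 60, 1200, 20)
  b <- detect_network_bursts(r, active_ids = 1:60)
  expect_equal(nrow(b), 0)
  r2 <- raster_from_events(1:10, 500L + (0:9), 60, 1200, 20)
  b2 <- detect_network_bursts(r2, active_ids = 1:60)
  expect_equal(nrow(b2), 1)
})

test_that("burst detection is idempotent", {
  cu <- simulate_raster(tiny_params(), seed = 31, bursty = TRUE)
  a <- detect_network_bursts(cu$raster, active_ids = cu$active_ids)
  b <- detect_network_bursts(cu$raster, active_ids = cu$active_ids)
  expect_identical(a$onset, b$onset)
  expect_identical(a$offset, b$offset)
})

test_that("independent-spike fraction matches the all-pairs oracle", {
  set.seed(55)
  ev <- which(matrix(runif(200 * 2000) < 0.002, 200), arr.ind = TRUE)
  r <- raster_from_events(ev[, 1], ev[, 2], 200, 2000, 20)
  got <- independent_spike_fraction(r)
  # O(n^2) oracle: a spike is independent iff no other spike within 1 frame
  ev2 <- r$events
  indep <- vapply(seq_len(nrow(ev2)), function(i) {
    d <- abs(ev2$frame - ev2$frame[i]) <= 1
    sum(d) == 1L
  }, TRUE)
  expect_equal(got, mean(indep))
})

test_that("independence edge cases: lone spike, same-frame pair, empty raster", {
  expect_equal(independent_spike_fraction(
    raster_from_events(5, 100, 10, 1000)), 1)
  expect_equal(independent_spike_fraction(
    raster_from_events(c(1, 2), c(100, 100), 10, 1000)), 0)
  expect_true(is.na(independent_spike_fraction(spike_raster(NULL, 10, 100))))
})

test_that("adding coincident spikes never raises the independent fraction", {
  set.seed(77)
  base <- data.frame(neuron = 1:20, frame = seq(10, 1900, length.out = 20))
  r <- spike_raster(base, 40, 2000, 20)
  f0 <- independent_spike_fraction(r)
  for (k in 1:5) {
    base <- rbind(base, data.frame(neuron = 20 + k,
                                   frame = base$frame[k]))
    r2 <- spike_raster(base, 40, 2000, 20)
    f1 <- independent_spike_fraction(r2)
    expect_lte(f1, f0)
    f0 <- f1
  }
})

test_that("planted IBI, participation and duration are recovered from preset rasters", {
  for (preset in c("WT-STR", "HD-STR", "WT-CTX", "HD-CTX", "BIC-like")) {
    p <- get_preset(preset, n_rois = 700)
    cu <- simulate_raster(p, seed = 61, bursty = TRUE)
    b <- detect_network_bursts(cu$raster, active_ids = cu$active_ids)
    n_active <- length(cu$active_ids)
    planted_ibi <- mean(diff(cu$schedule$onset))
    got_ibi <- mean(diff(b$onset)) / p$frame_rate
    expect_lt(abs(got_ibi - planted_ibi) / planted_ibi, 0.10,
              label = sprintf("%s IBI", preset))
    planted_part <- 100 * round(p$burst_participation * n_active) / n_active
    got_part <- mean(100 * b$n_participants / n_active)
    expect_lt(abs(got_part - planted_part) / planted_part, 0.10,
              label = sprintf("%s participation", preset))
    got_dur <- mean(b$duration)
    # cortical presets run at the isolation-packing limit of the background
    # rate, which blurs burst edges slightly
    dur_tol <- if (grepl("CTX", preset)) 0.25 else 0.15
    expect_lt(abs(got_dur - p$burst_duration) / p$burst_duration, dur_tol,
              label = sprintf("%s duration", preset))
  }
  # NMDA-like cultures schedule no coherent bursts; any detector output on
  # them reflects chance background coincidences only
  nm <- simulate_raster(get_preset("NMDA-like", n_rois = 700), seed = 61)
  expect_equal(nrow(nm$schedule), 0)
  expect_equal(nm$counts$burst, 0)
})

test_that("activity summary computes the field-of-view observables", {
  # 600 s raster with 3780 spikes: global rate 6.3 spikes/s
  set.seed(5)
  ev <- data.frame(neuron = sample(30, 3780, TRUE),
                   frame = sample(12000, 3780, TRUE))
  r <- spike_raster(unique(ev), 30, 12000, 20)
  s <- activity_summary(r, labels = rep("neuron", 30), bursts = NULL)
  expect_equal(s$global_rate, nrow(r$events) / 600)
  # one burst only: IBI undefined, culture non-bursty
  r1 <- raster_from_events(1:12, 500L + (0:11), 60, 12000, 20)
  b1 <- detect_network_bursts(r1, active_ids = 1:60)
  s1 <- activity_summary(r1, labels = rep("neuron", 60), bursts = b1)
  expect_true(is.na(s1$mean_ibi))
  expect_false(s1$bursty)
  # percentages live in [0, 100]
  expect_true(s$percent_active >= 0 && s$percent_active <= 100)
})

test_that("percent active uses cell ROIs as denominator and the 2-spike rule", {
  labels <- c(rep("neuron", 4), rep("silent", 4), rep("glia", 2))
  ev <- data.frame(neuron = c(1, 1, 2, 2, 3), frame = c(10, 50, 90, 130, 170))
  r <- spike_raster(ev, 10, 1200, 20)
  s <- activity_summary(r, labels, bursts = NULL)
  # neurons 1-2 have >= 2 spikes; denominator is 8 cells (glia excluded)
  expect_equal(s$percent_active, 100 * 2 / 8)
})
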