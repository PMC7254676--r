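# Shared fixtures and caches for the test suite. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# small, fast parameter set used by unit tests that don't need the full
# preset-scale culture
tiny_params <- function(...) {
  base <- list(n_rois = 40, frac_active = 0.5, frac_glia = 0.1,
               duration = 60, frame_rate = 20, mean_ibi = 8,
               burst_participation = 0.6, burst_duration = 0.5,
               spikes_per_burst_neuron = 2, independent_rate = 0.05,
               n_modules = 2, p_intra = 0.4, p_inter = 0.05)
  do.call(generator_params, utils::modifyList(base, list(...)))
}

# cache expensive artefacts (full-chain group runs, default classifier)
# across test files within one session
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

test_classifier <- function() {
  cached("clf", default_trace_classifier())
}

# Full trace-level chain over a seeded batch of one preset, with network
# inference on cultures whose reconstruction yields > 25 active neurons.
# Used by the calibration round-trip tests.
cached_group_run <- function(preset, n = 10, seed = 7L, network = TRUE) {
  cached(sprintf("run_%s_%d_%d", preset, n, seed), {
    params <- get_preset(preset)
    clf <- test_classifier()
    cultures <- simulate_batch(params, n, seed = seed)
    lapply(cultures, function(cu) {
      res <- analyze_culture(cu, classifier = clf, network = network)
      res$culture <- cu
      res
    })
  })
}

group_metric <- function(runs, f) {
  vapply(runs, f, numeric(1))
}
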