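#' Analyse one culture from rendered traces to summary statistics
#'
#' Runs the trace-level analysis chain on a synthetic culture: render raw
#' fluorescence traces, baseline-correct and normalize them, classify every
#' ROI trace (neuron / glia / silent), reconstruct spikes from the
#' neuron-labelled traces by kernel peeling, detect network bursts, and
#' compute the collective-activity summary. Optionally infers the effective
#' network with Generalized Transfer Entropy and summarises its topology
#' (refused, with an explicit status, when 25 or fewer active neurons are
#' available).
#'
#' @param culture A [simulate_raster()] result.
#' @param classifier A `trace_classifier`; default [default_trace_classifier()].
#' @param network Run GTE network inference and topology.
#' @param kernel The [calcium_kernel()] used for peeling.
#' @param seed Integer seed (rendering noise, Louvain restarts).
#' @return A list with `labels`, `raster`, `bursts`, `summary`, and when
#'   requested `network` (an `effective_network` or refusal status) and
#'   `topology`.
#' @export
analyze_culture <- function(culture, classifier = NULL, network = FALSE,
                            kernel = NULL, seed = culture$seed) {
  p <- culture$params
  if (is.null(kernel))
    kernel <- calcium_kernel(p$kernel_amplitude, p$kernel_decay)
  if (is.null(classifier)) classifier <- default_trace_classifier()
  traces <- render_traces(culture, seed = seed)
  tm <- normalize_traces(traces$raw, frame_rate = p$frame_rate)
  feats <- featurize_traces(tm)
  labels <- classify_traces(classifier, feats)$label
  neuron_idx <- which(labels == "neuron" & tm$valid)
  raster <- reconstruct_raster(tm, kernel, rois = neuron_idx)
  counts <- spike_counts(raster)
  active <- intersect(neuron_idx, which(counts >= 2L))
  bursts <- detect_network_bursts(raster, active_ids = active)
  summ <- activity_summary(raster, labels, bursts)
  out <- list(labels = labels, raster = raster, bursts = bursts,
              summary = summ)
  if (network) {
    net <- infer_effective_network(raster, active_ids = active)
    out$network <- net
    if (inherits(net, "effective_network"))
      out$topology <- topology_summary(net, seed = seed %||% 1L)
  }
  out
}

#' Analyse one culture through the movie stage
#'
#' Full imaging front-end: render the fluorescence movie (in chunks, so long
#' recordings never materialise as a single array), detect ROIs on the
#' time-averaged image, extract and normalize per-ROI traces, then continue
#' with classification, peeling, burst detection and the activity summary as
#' in [analyze_culture()]. Rendering is deterministic per chunk, so the
#' averaging pass and the trace-extraction pass see identical movies.
#'
#' @param culture A [simulate_raster()] result.
#' @param layout A [make_roi_layout()]; default builds one sized to the
#'   culture.
#' @param image_size Image side (pixels) when building a default layout.
#' @param chunk Frames rendered per chunk.
#' @param classifier A `trace_classifier`.
#' @param seed Integer seed.
#' @param ... Movie rendering options passed to [render_movie()].
#' @return As [analyze_culture()], plus `rois` (the detected ROI set) and
#'   `n_rois_detected`.
#' @export
analyze_culture_movie <- function(culture, layout = NULL, image_size = 140,
                                  chunk = 1000L, classifier = NULL,
                                  seed = culture$seed, ...) {
  p <- culture$params
  if (is.null(classifier)) classifier <- default_trace_classifier()
  if (is.null(layout))
    layout <- make_roi_layout(p$n_rois, image_size, seed = seed)
  traces <- render_traces(culture, seed = seed)
  nf <- ncol(traces$raw)
  starts <- seq(1L, nf, by = chunk)

  # pass 1: time-averaged image
  acc <- NULL
  for (ci in seq_along(starts)) {
    idx <- starts[ci]:min(starts[ci] + chunk - 1L, nf)
    mv <- render_movie(traces, layout, seed = (seed %||% 0L) * 131L + ci,
                       frame_idx = idx, field_seed = (seed %||% 0L) + 17L, ...)
    s <- rowSums(mv$data, dims = 2)
    acc <- if (is.null(acc)) s else acc + s
  }
  mean_img <- acc / nf
  rois <- detect_rois(mean_img)
  if (!length(rois$pixels))
    stop("no ROIs detected on the time-averaged image")

  # pass 2: identical rendering, extract ROI-pixel means
  f <- matrix(NA_real_, length(rois$pixels), nf)
  for (ci in seq_along(starts)) {
    idx <- starts[ci]:min(starts[ci] + chunk - 1L, nf)
    mv <- render_movie(traces, layout, seed = (seed %||% 0L) * 131L + ci,
                       frame_idx = idx, field_seed = (seed %||% 0L) + 17L, ...)
    f[, idx] <- extract_traces(mv, rois)
  }

  tm <- normalize_traces(f, frame_rate = p$frame_rate)
  feats <- featurize_traces(tm)
  labels <- classify_traces(classifier, feats)$label
  kernel <- calcium_kernel(p$kernel_amplitude, p$kernel_decay)
  neuron_idx <- which(labels == "neuron" & tm$valid)
  raster <- reconstruct_raster(tm, kernel, rois = neuron_idx)
  counts <- spike_counts(raster)
  active <- intersect(neuron_idx, which(counts >= 2L))
  bursts <- detect_network_bursts(raster, active_ids = active)
  summ <- activity_summary(raster, labels, bursts)
  list(rois = rois, n_rois_detected = length(rois$pixels), labels = labels,
       raster = raster, bursts = bursts, summary = summ)
}

#' Run the full pipeline over a batch of simulated cultures
#'
#' Orchestrates simulate -> render -> normalize -> classify -> peel ->
#' bursts -> summary (-> GTE network -> topology) for `n_cultures` seeded
#' cultures of one preset, and collects one summary row per culture plus
#' group-level mean/SEM/SD statistics. Reruns with the same config are
#' deterministic.
#'
#' @param config A list: `preset` (name) or `params` (a
#'   [generator_params()]), `n_cultures`, `seed`, `network` (logical),
#'   `movie` (logical: run the imaging front-end), and optional stage
#'   parameter overrides (`image_size`, `chunk`).
#' @return A list with `cultures` (a data frame, one row per culture),
#'   `group` (mean/sem/sd per observable), `refusals` (network-inference
#'   status per culture) and the expanded `config`.
#' @export
run_pipeline <- function(config) {
  params <- config$params %||% get_preset(config$preset %||% "WT-STR")
  n <- config$n_cultures %||% 10L
  seed <- config$seed %||% 1L
  network <- isTRUE(config$network)
  movie <- isTRUE(config$movie)
  classifier <- default_trace_classifier()
  cultures <- simulate_batch(params, n, seed = seed)
  rows <- vector("list", n)
  refusals <- character(n)
  for (i in seq_len(n)) {
    cu <- cultures[[i]]
    res <- if (movie) {
      analyze_culture_movie(cu, image_size = config$image_size %||% 140,
                            chunk = config$chunk %||% 1000L,
                            classifier = classifier)
    } else {
      analyze_culture(cu, classifier = classifier, network = network)
    }
    topo <- res$topology
    if (network && !movie) {
      refusals[i] <- if (inherits(res$network, "effective_network"))
        "ok" else res$network$reason %||% "refused"
      if (is.null(topo))
        topo <- list(global_efficiency = NA_real_, Q = NA_real_,
                     Q_ratio = NA_real_, mean_community_size = NA_real_,
                     n_connector_hubs = NA_integer_)
    }
    rows[[i]] <- summary_row(res$summary, topo, culture = i,
                             seed = cu$seed, bursty_planted = cu$bursty)
  }
  tab <- do.call(rbind, rows)
  num <- vapply(tab, is.numeric, TRUE) &
    !names(tab) %in% c("culture", "seed")
  group <- t(vapply(tab[num], group_summary, numeric(4)))
  list(cultures = tab, group = group, refusals = refusals,
       config = list(params = params, n_cultures = n, seed = seed,
                     network = network, movie = movie))
}
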