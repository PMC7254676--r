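#' Simulate a ground-truth neuronal culture
#'
#' Draws a complete synthetic culture: ROI roles (active neuron, silent cell,
#' glia), a planted modular directed network over the active neurons, a
#' network-burst schedule, and the binary spike raster. Everything needed to
#' validate the downstream analysis chain against ground truth is returned.
#'
#' Burst onsets follow a renewal process with gamma-distributed inter-onset
#' intervals (mean `mean_ibi`, shape `ibi_shape`). Each burst recruits
#' `round(burst_participation * n_active)` participants, drawn without
#' replacement with weight `participation_weight` for members of the burst's
#' seed module (one module per burst, sampled uniformly), so that co-bursting
#' carries the planted community structure. Participants emit
#' `spikes_per_burst_neuron` spikes at distinct frames uniformly jittered in
#' the `burst_duration` window after onset.
#'
#' Background ("independent") spikes are drawn with expected count
#' `independent_rate * n_active * duration` and placed by uniform sampling
#' of minimum-gap frame sets: every background spike sits at least three
#' frames from every other spike, i.e. isolated in the sense of the
#' independent-spike statistic, with one frame of slack so that single-frame
#' reconstruction jitter cannot create spurious coincidences. If the
#' requested rate exceeds the isolation packing capacity, the excess is
#' placed on free frames without the isolation guarantee (and counted in
#' `counts$overflow`).
#'
#' @param params A [generator_params()] set.
#' @param network Optional [make_ground_truth_network()] result over the
#'   active neurons; its size must equal the number of active neurons.
#'   Generated automatically when `NULL` and `n_modules >= 1`.
#' @param seed Integer seed (defaults to `params$seed`).
#' @param bursty Logical override of the culture's bursty state; when `NULL`
#'   the state is drawn with probability `params$bursty_fraction`.
#' @return An object of class `culture`: a list with elements `params`,
#'   `roles` (per-ROI `"neuron"`, `"silent"` or `"glia"`), `active_ids` (ROI
#'   indices of the active neurons), `network`, `module_of_roi`, `bursty`,
#'   `schedule` (data frame of onset/offset seconds with a `participants`
#'   list-column of ROI ids), `raster` (a [spike_raster()]) and `counts`
#'   (burst / independent / overflow spike bookkeeping).
#' @seealso [simulate_batch()], [render_traces()]
#' @export
simulate_raster <- function(params, network = NULL, seed = params$seed,
                            bursty = NULL) {
  validate_generator_params(params)
  with_seed(seed, {
    n_frames <- as.integer(round(params$duration * params$frame_rate))
    n_glia <- as.integer(round(params$frac_glia * params$n_rois))
    n_cells <- params$n_rois - n_glia
    n_active <- as.integer(round(params$frac_active * n_cells))

    roles <- rep("silent", params$n_rois)
    ord <- sample.int(params$n_rois)
    glia_ids <- ord[seq_len(n_glia)]
    active_ids <- sort(ord[n_glia + seq_len(n_active)])
    roles[glia_ids] <- "glia"
    roles[active_ids] <- "neuron"

    if (is.null(network)) {
      if (n_active > 0) {
        network <- make_ground_truth_network(
          n_active, min(params$n_modules, max(n_active, 1L)),
          params$p_intra, params$p_inter)
      }
    } else if (nrow(network$adjacency) != n_active) {
      stop(sprintf("network has %d nodes but the culture has %d active neurons",
                   nrow(network$adjacency), n_active))
    }
    module_of_roi <- rep(NA_integer_, params$n_rois)
    if (n_active > 0) module_of_roi[active_ids] <- network$modules

    if (is.null(bursty)) bursty <- stats::runif(1) < params$bursty_fraction

    ## ---- burst schedule -------------------------------------------------
    burst_events <- NULL
    schedule <- data.frame(onset = numeric(0), offset = numeric(0))
    schedule$participants <- list()
    if (bursty && n_active > 0 && is.finite(params$mean_ibi)) {
      scale <- params$mean_ibi / params$ibi_shape
      onsets <- numeric(0)
      t <- stats::rgamma(1, shape = params$ibi_shape, scale = scale)
      while (t < params$duration - params$burst_duration) {
        onsets <- c(onsets, t)
        t <- t + stats::rgamma(1, shape = params$ibi_shape, scale = scale)
      }
      n_part <- max(1L, round(params$burst_participation * n_active))
      shp <- params$recruitment_shape %||% Inf
      propensity <- if (is.finite(shp))
        stats::rgamma(n_active, shape = shp, rate = shp) else rep(1, n_active)
      win_frames <- max(1L, round(params$burst_duration * params$frame_rate))
      parts <- vector("list", length(onsets))
      ev_n <- vector("list", length(onsets))
      ev_f <- vector("list", length(onsets))
      for (b in seq_along(onsets)) {
        seed_mod <- sample.int(length(unique(network$modules)), 1)
        w <- propensity *
          ifelse(network$modules == seed_mod, params$participation_weight, 1)
        sel <- sample.int(n_active, min(n_part, n_active), prob = w)
        parts[[b]] <- sort(active_ids[sel])
        onset_f <- as.integer(round(onsets[b] * params$frame_rate)) + 1L
        k <- min(params$spikes_per_burst_neuron, win_frames)
        fr <- vapply(seq_along(sel), function(i)
          onset_f - 1L + sort(sample.int(win_frames, k)), integer(k))
        ev_n[[b]] <- rep(active_ids[sel], each = k)
        ev_f[[b]] <- as.integer(fr)
      }
      schedule <- data.frame(onset = onsets,
                             offset = onsets + params$burst_duration)
      schedule$participants <- parts
      burst_events <- data.frame(neuron = unlist(ev_n), frame = unlist(ev_f))
      burst_events <- burst_events[burst_events$frame <= n_frames, ,
                                   drop = FALSE]
    }

    ## ---- independent (isolated) background spikes -----------------------
    rate <- if (bursty) params$independent_rate else
      params$independent_rate_nonbursty
    n_bg_target <- if (n_active > 0)
      stats::rpois(1, rate * n_active * params$duration) else 0L
    blocked <- logical(n_frames)
    blocked[seq_len(min(2L, n_frames))] <- TRUE # recording-edge guard
    if (!is.null(burst_events) && nrow(burst_events)) {
      bf <- unique(burst_events$frame)
      for (d in -2:2) {
        idx <- bf + d
        idx <- idx[idx >= 1L & idx <= n_frames]
        blocked[idx] <- TRUE
      }
    }
    free0 <- which(!blocked)
    accepted <- integer(0)
    overflow <- integer(0)
    if (n_bg_target > 0 && length(free0) > 0) {
      placed <- place_isolated_frames(blocked, n_bg_target)
      accepted <- placed$frames
      if (placed$short > 0) {
        overflow <- sample(free0, min(placed$short, length(free0)),
                           replace = TRUE)
      }
    }
    bg_frames <- c(accepted, overflow)
    bg_events <- NULL
    if (length(bg_frames)) {
      bg_events <- data.frame(
        neuron = active_ids[sample.int(n_active, length(bg_frames),
                                       replace = TRUE)],
        frame = as.integer(bg_frames))
    }

    events <- rbind(burst_events, bg_events)
    raster <- spike_raster(events, n_neurons = params$n_rois,
                           n_frames = n_frames,
                           frame_rate = params$frame_rate)
    counts <- list(
      burst = if (is.null(burst_events)) 0L else nrow(burst_events),
      independent = length(accepted),
      overflow = length(overflow))

    structure(list(params = params, roles = roles, active_ids = active_ids,
                   network = network, module_of_roi = module_of_roi,
                   bursty = bursty, schedule = schedule, raster = raster,
                   counts = counts, seed = seed),
              class = "culture")
  })
}

#' @export
print.culture <- function(x, ...) {
  cat(sprintf("Synthetic culture: %d ROIs (%d active neurons), %s\n",
              x$params$n_rois, length(x$active_ids),
              if (x$bursty) sprintf("%d scheduled bursts", nrow(x$schedule))
              else "non-bursty"))
  print(x$raster)
  invisible(x)
}

#' Simulate a batch of cultures with stratified bursty allocation
#'
#' Generates `n` cultures with seeds `seed + 1, ..., seed + n`. Instead of
#' drawing each culture's bursty state independently, exactly
#' `round(bursty_fraction * n)` cultures are made bursty (allocation order
#' randomised from `seed`), which reduces small-batch variance of the
#' group-level means while leaving the per-culture generative model unchanged.
#'
#' @param params A [generator_params()] set.
#' @param n Number of cultures.
#' @param seed Integer base seed.
#' @return A list of `culture` objects.
#' @export
simulate_batch <- function(params, n, seed = 1L) {
  n_bursty <- round(params$bursty_fraction * n)
  state <- with_seed(seed, sample(rep(c(TRUE, FALSE),
                                      c(n_bursty, n - n_bursty))))
  lapply(seq_len(n), function(i)
    simulate_raster(params, seed = seed + i, bursty = state[i]))
}

# Uniformly samples `k` frames with pairwise separation >= 3 from the
# unblocked frames. Within each contiguous free segment of length L, a set
# of j such frames is drawn exactly uniformly via the standard bijection
# between min-gap subsets and plain j-subsets of L - 2*(j-1) positions;
# counts are allocated across segments proportionally to segment length,
# capped at each segment's packing capacity. Returns the frames and the
# shortfall (`short` > 0 when `k` exceeds the total isolation capacity).
place_isolated_frames <- function(blocked, k) {
  r <- rle(!blocked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg_start <- starts[r$values]
  seg_len <- r$lengths[r$values]
  if (!length(seg_len) || k <= 0)
    return(list(frames = integer(0), short = max(0L, k)))
  cap <- (seg_len + 2L) %/% 3L
  k_eff <- min(k, sum(cap))
  alloc <- pmin(cap, floor(k_eff * seg_len / sum(seg_len)))
  left <- k_eff - sum(alloc)
  while (left > 0L) {
    slack <- which(alloc < cap)
    pick <- slack[sample.int(length(slack), min(left, length(slack)))]
    alloc[pick] <- alloc[pick] + 1L
    left <- k_eff - sum(alloc)
  }
  frames <- vector("list", length(seg_len))
  for (i in seq_along(seg_len)) {
    ki <- alloc[i]
    if (!ki) next
    pos <- sort(sample.int(seg_len[i] - 2L * (ki - 1L), ki)) +
      2L * (seq_len(ki) - 1L)
    frames[[i]] <- seg_start[i] - 1L + pos
  }
  list(frames = unlist(frames) %||% integer(0), short = k - k_eff)
}
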