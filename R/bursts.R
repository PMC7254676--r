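#' Two-threshold (Schmitt trigger) segmentation
#'
#' Segments a signal with hysteresis: a segment opens at the first sample
#' `>= hi` and closes at the last sample before the signal falls `< lo`.
#' A segment still open at the end of the signal closes at the final sample.
#'
#' @param signal Numeric vector.
#' @param hi,lo Upper and lower thresholds (`hi >= lo`).
#' @return Integer matrix with columns `open`, `close` (sample indices).
#' @export
schmitt_segments <- function(signal, hi, lo) {
  if (lo > hi) stop("'lo' must not exceed 'hi'")
  n <- length(signal)
  out <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("open", "close")))
  if (!n) return(out)
  opens <- which(signal >= hi)
  closes <- which(signal < lo)
  pos <- 1L
  res <- list()
  while (length(opens)) {
    o <- opens[opens >= pos]
    if (!length(o)) break
    o <- o[1L]
    cl <- closes[closes > o]
    c_at <- if (length(cl)) cl[1L] - 1L else n
    res[[length(res) + 1L]] <- c(o, c_at)
    pos <- c_at + 2L  # first sample after the closing drop
    if (!length(cl)) break
  }
  if (length(res)) out <- do.call(rbind, res)
  dimnames(out) <- list(NULL, c("open", "close"))
  out
}

# population-activity signal: number of unique neurons with >= 1 spike in the
# trailing window of `w` frames, computed from the sparse events in O(spikes)
activity_signal <- function(raster, window_frames) {
  n <- raster$n_frames
  w <- as.integer(window_frames)
  d <- numeric(n + 1L)
  ev <- raster$events
  if (nrow(ev)) {
    for (fs in split(ev$frame, ev$neuron)) {
      fs <- sort(fs)
      # merge per-neuron coverage intervals [f, f+w-1] into runs
      new_run <- c(TRUE, diff(fs) >= w)
      starts <- fs[new_run]
      run_id <- cumsum(new_run)
      last_of_run <- vapply(split(fs, run_id), max, numeric(1))
      ends <- pmin(as.integer(last_of_run) + w - 1L, n)
      d[starts] <- d[starts] + 1
      d[ends + 1L] <- d[ends + 1L] - 1
    }
  }
  cumsum(d[seq_len(n)])
}

#' Detect network bursts with a Schmitt trigger
#'
#' Computes the population-activity signal (number of unique neurons spiking
#' in the trailing `window` seconds at each frame), segments it with a
#' two-threshold trigger at `hi` and `lo` fractions of the active-neuron
#' count, merges bursts separated by less than `merge_gap` seconds, and
#' discards bursts with fewer than `min_participants` participating neurons.
#'
#' Because both trigger thresholds act on a trailing window, the raw trigger
#' times lag the underlying spiking. Burst onset/offset are therefore snapped
#' to the burst core: the first and last frame, within the lag-corrected
#' triggered span, carrying at least `core_min` coincident spikes (falling
#' back to the first/last spike frame in the span when no frame reaches
#' `core_min`); three coincident spikes distinguish genuine burst frames
#' from chance background coincidences even in dense recordings. Participants are the neurons spiking within `[onset,
#' offset]`.
#'
#' @param raster A [spike_raster()].
#' @param active_ids Neuron ids forming the active set (denominator of the
#'   percentage thresholds). Defaults to neurons with >= 2 spikes.
#' @param window Activity window in seconds.
#' @param hi,lo Upper/lower Schmitt thresholds as fractions of the active
#'   count.
#' @param merge_gap Bursts closer than this (seconds) are merged.
#' @param min_participants Minimum number of participating neurons.
#' @param core_min Minimum coincident spikes defining the burst core.
#' @return An object of class `network_bursts`: a data frame with columns
#'   `onset`, `offset` (frames), `duration` (s), `n_participants`,
#'   `spikes_per_participant`, plus a `participants` list-column; attributes
#'   `n_active` and `frame_rate`.
#' @export
detect_network_bursts <- function(raster, active_ids = NULL, window = 1,
                                  hi = 0.10, lo = 0.05, merge_gap = 0.5,
                                  min_participants = 10, core_min = 3) {
  fr <- raster$frame_rate
  if (is.null(active_ids))
    active_ids <- which(spike_counts(raster) >= 2L)
  n_active <- length(active_ids)
  empty <- structure(
    data.frame(onset = integer(0), offset = integer(0), duration = numeric(0),
               n_participants = integer(0),
               spikes_per_participant = numeric(0)),
    class = c("network_bursts", "data.frame"),
    n_active = n_active, frame_rate = fr)
  if (n_active == 0L || nrow(raster$events) == 0L) return(empty)

  w <- max(1L, as.integer(round(window * fr)))
  sig <- activity_signal(raster, w)
  seg <- schmitt_segments(sig, hi * n_active, lo * n_active)
  if (!nrow(seg)) return(empty)

  # merge trigger segments separated by less than merge_gap seconds (single
  # left-to-right pass; merging is idempotent because gaps only grow after)
  gap_frames <- merge_gap * fr
  mseg <- seg[1L, , drop = FALSE]
  if (nrow(seg) > 1L) {
    for (b in 2L:nrow(seg)) {
      last <- nrow(mseg)
      if (seg[b, 1L] - mseg[last, 2L] < gap_frames) {
        mseg[last, 2L] <- max(mseg[last, 2L], seg[b, 2L])
      } else {
        mseg <- rbind(mseg, seg[b, , drop = FALSE])
      }
    }
  }

  # correct for the trailing-window lag and snap each burst to its core
  ev <- raster$events
  per_frame <- tabulate(ev$frame, nbins = raster$n_frames)
  merged <- matrix(NA_integer_, nrow(mseg), 2)
  for (b in seq_len(nrow(mseg))) {
    span <- max(1L, mseg[b, 1L] - w + 1L):mseg[b, 2L]
    core <- span[per_frame[span] >= core_min]
    if (!length(core)) core <- span[per_frame[span] > 0L]
    if (!length(core)) next
    merged[b, ] <- range(core)
  }
  merged <- merged[!is.na(merged[, 1L]), , drop = FALSE]
  if (!nrow(merged)) return(empty)

  parts <- vector("list", nrow(merged))
  n_part <- integer(nrow(merged))
  spp <- numeric(nrow(merged))
  for (b in seq_len(nrow(merged))) {
    inside <- ev$frame >= merged[b, 1L] & ev$frame <= merged[b, 2L]
    parts[[b]] <- sort(unique(ev$neuron[inside]))
    n_part[b] <- length(parts[[b]])
    spp[b] <- if (n_part[b]) sum(inside) / n_part[b] else 0
  }
  keep <- n_part >= min_participants
  out <- data.frame(onset = merged[keep, 1L], offset = merged[keep, 2L],
                    duration = (merged[keep, 2L] - merged[keep, 1L] + 1L) / fr,
                    n_participants = n_part[keep],
                    spikes_per_participant = spp[keep])
  out$participants <- parts[keep]
  structure(out, class = c("network_bursts", "data.frame"),
            n_active = n_active, frame_rate = fr)
}

#' @export
print.network_bursts <- function(x, ...) {
  cat(sprintf("Network bursts: %d (active set: %d neurons)\n",
              nrow(x), attr(x, "n_active")))
  if (nrow(x)) print.data.frame(x[setdiff(names(x), "participants")])
  invisible(x)
}

#' Fraction of independent spikes
#'
#' A spike is independent when no other spike occurs anywhere in the system
#' within one frame (50 ms at 20 frames/s) of it, i.e. the spike's frame and
#' both neighbouring frames carry no other spike. Same-frame spikes of the
#' same neuron cannot occur in a binary raster, so no same-neuron exclusion
#' is needed.
#'
#' @param raster A [spike_raster()].
#' @return Fraction in `[0, 1]`, or `NA` for an empty raster.
#' @export
independent_spike_fraction <- function(raster) {
  ev <- raster$events
  if (!nrow(ev)) return(NA_real_)
  cnt <- tabulate(ev$frame, nbins = raster$n_frames)
  pad <- c(0L, cnt, 0L)
  f <- ev$frame + 1L # index into padded counts
  indep <- pad[f] == 1L & pad[f - 1L] == 0L & pad[f + 1L] == 0L
  mean(indep)
}

#' Collective-activity summary of a culture recording
#'
#' Computes the ensemble observables of a recording: percentage of active
#' neurons (neuron-labelled ROIs with at least `theta_active` reconstructed
#' spikes, over all cell ROIs, i.e. neuron- or silent-labelled), per-burst
#' participation, mean inter-burst interval (onset-to-onset), burst duration
#' and amplitude (spikes per participating neuron per burst), global activity
#' rate (total spikes per second in the field of view), independent-spike
#' fraction, the bursty flag (mean IBI below `bursty_cutoff`), and
#' single-cell statistics (per-neuron rate, inter-spike interval, single-cell
#' burst rate and burst interval; a single-cell burst is a run of >= 3 spikes
#' with gaps below 0.5 s).
#'
#' @param raster A [spike_raster()] of reconstructed spikes.
#' @param labels Per-ROI labels (`"neuron"`, `"glia"`, `"silent"`), e.g. from
#'   [classify_traces()]; `NULL` treats every ROI as a neuron.
#' @param bursts A [detect_network_bursts()] result for this raster.
#' @param theta_active Minimum spikes for a neuron to count as active.
#' @param bursty_cutoff Bursty-culture IBI cutoff in seconds.
#' @return An object of class `activity_summary` (a named list).
#' @export
activity_summary <- function(raster, labels = NULL, bursts = NULL,
                             theta_active = 2, bursty_cutoff = 45) {
  fr <- raster$frame_rate
  duration <- raster$n_frames / fr
  if (is.null(labels)) labels <- rep("neuron", raster$n_neurons)
  labels <- as.character(labels)
  if (length(labels) != raster$n_neurons)
    stop("one label per ROI required")
  counts <- spike_counts(raster)
  is_cell <- labels %in% c("neuron", "silent")
  is_active <- labels == "neuron" & counts >= theta_active
  percent_active <- if (sum(is_cell) > 0)
    100 * sum(is_active) / sum(is_cell) else NA_real_

  if (is.null(bursts))
    bursts <- detect_network_bursts(raster, active_ids = which(is_active))
  n_active_det <- attr(bursts, "n_active")
  nb <- nrow(bursts)
  percent_in_bursts <- if (nb > 0 && n_active_det > 0)
    mean(100 * bursts$n_participants / n_active_det) else NA_real_
  mean_ibi <- if (nb >= 2) mean(diff(bursts$onset)) / fr else NA_real_
  burst_duration <- if (nb > 0) mean(bursts$duration) else NA_real_
  burst_amplitude <- if (nb > 0) mean(bursts$spikes_per_participant)
    else NA_real_
  global_rate <- sum(counts) / duration
  indep <- independent_spike_fraction(raster)
  bursty <- !is.na(mean_ibi) && mean_ibi < bursty_cutoff

  # single-cell statistics over active neurons
  ev <- raster$events
  rate_i <- isi_i <- scb_rate_i <- scb_ibi_i <- numeric(0)
  act_ids <- which(is_active)
  if (length(act_ids)) {
    by_n <- split(ev$frame, ev$neuron)
    by_n <- by_n[names(by_n) %in% as.character(act_ids)]
    rate_i <- vapply(by_n, length, 0L) / duration
    isi_i <- vapply(by_n, function(f) {
      if (length(f) < 2) NA_real_ else mean(diff(sort(f))) / fr
    }, 0)
    scb <- lapply(by_n, function(f) {
      f <- sort(f)
      grp <- cumsum(c(TRUE, diff(f) >= 0.5 * fr))
      sz <- tabulate(grp)
      onset_f <- f[!duplicated(grp)][sz >= 3]
      onset_f
    })
    scb_rate_i <- vapply(scb, length, 0L) / duration
    scb_ibi_i <- vapply(scb, function(o) {
      if (length(o) < 2) NA_real_ else mean(diff(o)) / fr
    }, 0)
  }

  structure(list(
    percent_active = percent_active,
    percent_in_bursts = percent_in_bursts,
    mean_ibi = mean_ibi,
    burst_duration = burst_duration,
    burst_amplitude = burst_amplitude,
    global_rate = global_rate,
    independent_fraction = 100 * indep,
    n_bursts = nb,
    bursty = bursty,
    n_active = sum(is_active),
    n_cells = sum(is_cell),
    per_neuron = list(rate = rate_i, isi = isi_i,
                      burst_rate = scb_rate_i, burst_interval = scb_ibi_i),
    duration = duration), class = "activity_summary")
}

#' @export
print.activity_summary <- function(x, ...) {
  cat("Culture activity summary\n")
  cat(sprintf("  active neurons      : %d/%d (%.1f%%)\n", x$n_active,
              x$n_cells, x$percent_active))
  cat(sprintf("  network bursts      : %d (%s)\n", x$n_bursts,
              if (x$bursty) "bursty" else "non-bursty"))
  cat(sprintf("  mean IBI            : %s s\n",
              if (is.na(x$mean_ibi)) "undefined" else
                sprintf("%.1f", x$mean_ibi)))
  cat(sprintf("  burst participation : %s%%\n",
              if (is.na(x$percent_in_bursts)) "undefined" else
                sprintf("%.1f", x$percent_in_bursts)))
  cat(sprintf("  global rate         : %.2f spikes/s\n", x$global_rate))
  cat(sprintf("  independent spikes  : %s%%\n",
              if (is.na(x$independent_fraction)) "undefined" else
                sprintf("%.1f", x$independent_fraction)))
  invisible(x)
}

#' One summary row per culture for group-level tables
#' @param summary An [activity_summary()].
#' @param topology Optional [topology_summary()].
#' @param ... Extra identifying columns (genotype, region, phase, litter...).
#' @return A one-row data frame.
#' @export
summary_row <- function(summary, topology = NULL, ...) {
  row <- data.frame(...,
    percent_active = summary$percent_active,
    percent_in_bursts = summary$percent_in_bursts,
    mean_ibi = summary$mean_ibi,
    burst_duration = summary$burst_duration,
    burst_amplitude = summary$burst_amplitude,
    global_rate = summary$global_rate,
    independent_fraction = summary$independent_fraction,
    n_bursts = summary$n_bursts,
    bursty = summary$bursty,
    mean_neuron_rate = if (length(summary$per_neuron$rate))
      mean(summary$per_neuron$rate) else NA_real_,
    mean_neuron_isi = if (any(!is.na(summary$per_neuron$isi)))
      mean(summary$per_neuron$isi, na.rm = TRUE) else NA_real_,
    mean_cell_burst_rate = if (length(summary$per_neuron$burst_rate))
      mean(summary$per_neuron$burst_rate) else NA_real_,
    mean_cell_burst_interval = if (any(!is.na(summary$per_neuron$burst_interval)))
      mean(summary$per_neuron$burst_interval, na.rm = TRUE) else NA_real_)
  if (!is.null(topology)) {
    row$global_efficiency <- topology$global_efficiency
    row$modularity_q <- topology$Q
    row$intra_inter_ratio <- topology$Q_ratio
    row$mean_community_size <- topology$mean_community_size
    row$n_connector_hubs <- topology$n_connector_hubs
  }
  row
}
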