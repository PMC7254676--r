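#' Spike raster container
#'
#' Sparse binary neuron-by-frame spike raster. Events are stored as a
#' two-column data frame (`neuron`, `frame`); duplicates are collapsed so the
#' raster is strictly binary. One frame lasts `1/frame_rate` seconds (50 ms at
#' 20 frames/s).
#'
#' @param events Data frame with integer columns `neuron` and `frame`.
#' @param n_neurons,n_frames Raster dimensions.
#' @param frame_rate Frames per second.
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(events, n_neurons, n_frames, frame_rate = 20) {
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(neuron = integer(0), frame = integer(0))
  } else {
    events <- data.frame(neuron = as.integer(events$neuron),
                         frame = as.integer(events$frame))
    if (any(events$neuron < 1L) || any(events$neuron > n_neurons))
      stop("event neuron ids outside 1..n_neurons")
    if (any(events$frame < 1L) || any(events$frame > n_frames))
      stop("event frames outside 1..n_frames")
    events <- unique(events)
    events <- events[order(events$frame, events$neuron), , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(list(events = events, n_neurons = as.integer(n_neurons),
                 n_frames = as.integer(n_frames), frame_rate = frame_rate),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("Spike raster: %d neurons x %d frames (%.0f fps), %d spikes\n",
              x$n_neurons, x$n_frames, x$frame_rate, nrow(x$events)))
  invisible(x)
}

#' @export
as.matrix.spike_raster <- function(x, ...) {
  m <- matrix(0L, x$n_neurons, x$n_frames)
  if (nrow(x$events)) m[cbind(x$events$neuron, x$events$frame)] <- 1L
  m
}

#' Number of spikes per neuron
#' @param raster A [spike_raster()].
#' @return Integer vector of length `n_neurons`.
#' @export
spike_counts <- function(raster) {
  tabulate(raster$events$neuron, nbins = raster$n_neurons)
}

#' Write / read a spike raster as columnar text
#'
#' The on-disk format is a tab-separated table of (`neuron`, `frame`) events
#' with a `#`-comment header carrying the raster dimensions and frame rate,
#' so rasters from external reconstructions can enter the pipeline directly.
#'
#' @param raster A [spike_raster()].
#' @param path File path.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns a
#'   [spike_raster()].
#' @export
write_raster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_neurons=%d n_frames=%d frame_rate=%g",
                     raster$n_neurons, raster$n_frames, raster$frame_rate),
             con)
  utils::write.table(raster$events, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!grepl("^# *n_neurons=", hdr))
    stop("not a raster file: missing dimension header")
  gv <- function(k) as.numeric(sub(sprintf(".*%s=([0-9.eE+-]+).*", k), "\\1", hdr))
  ev <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  spike_raster(ev, n_neurons = gv("n_neurons"), n_frames = gv("n_frames"),
               frame_rate = gv("frame_rate"))
}

#' Circularly time-shift every spike train (surrogate data)
#'
#' Shifts each neuron's spike train by an independent uniform circular offset,
#' destroying cross-neuron timing relations while preserving every
#' single-train statistic. Standard surrogate for effective-connectivity
#' significance checks.
#'
#' @param raster A [spike_raster()].
#' @param seed Optional integer seed.
#' @return A [spike_raster()] of identical dimensions.
#' @export
shuffle_raster_circular <- function(raster, seed = NULL) {
  with_seed(seed, {
    ev <- raster$events
    if (nrow(ev)) {
      off <- sample.int(raster$n_frames, raster$n_neurons, replace = TRUE) - 1L
      ev$frame <- ((ev$frame - 1L + off[ev$neuron]) %% raster$n_frames) + 1L
    }
    spike_raster(ev, raster$n_neurons, raster$n_frames, raster$frame_rate)
  })
}
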