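#' Render fluorescence traces for a synthetic culture
#'
#' Turns the culture's spike raster into per-ROI fluorescence traces. Each
#' spike of an active neuron adds a calcium transient
#' `A * exp(-t / tau)` (`A = kernel_amplitude` % dF/F0,
#' `tau = kernel_decay` s) by linear superposition (non-saturating
#' indicator). Glia ROIs receive slow smooth waves (5--20% dF/F0, ~30 s
#' period); silent ROIs carry no signal. On top of the clean signal the raw
#' trace adds per-frame Gaussian noise (`noise_sd`), a slow baseline drift
#' (two sinusoids of 120 s and 300 s period plus a reflected random walk,
#' total amplitude `drift_amplitude`) and a per-ROI baseline fluorescence
#' level, giving `raw = F_base * (1 + (signal + drift + noise) / 100)`.
#'
#' @param culture A [simulate_raster()] result.
#' @param seed Integer seed for noise, drift and per-ROI baselines.
#' @param noise,drift Logical switches; disabling both yields a noiseless
#'   rendering whose normalized traces contain the exact kernel sums.
#' @return An object of class `trace_set`: list with `raw` and `clean`
#'   (ROI x frame matrices; `clean` is the noiseless signal in % dF/F0),
#'   `f_base` (per-ROI baseline level, arbitrary units), `frame_rate` and
#'   `roles`.
#' @export
render_traces <- function(culture, seed = culture$seed, noise = TRUE,
                          drift = TRUE) {
  p <- culture$params
  nf <- culture$raster$n_frames
  nr <- p$n_rois
  fr <- p$frame_rate
  tt <- (seq_len(nf) - 1L) / fr
  decay <- exp(-1 / (p$kernel_decay * fr))

  clean <- matrix(0, nr, nf)
  ev <- culture$raster$events
  by_neuron <- split(ev$frame, ev$neuron)
  for (nm in names(by_neuron)) {
    i <- as.integer(nm)
    x <- numeric(nf)
    x[by_neuron[[nm]]] <- p$kernel_amplitude
    clean[i, ] <- as.numeric(stats::filter(x, decay, method = "recursive"))
  }

  with_seed(seed, {
    glia_ids <- which(culture$roles == "glia")
    for (i in glia_ids) {
      amp <- stats::runif(1, 5, 20)
      period <- stats::runif(1, 25, 35)
      phase <- stats::runif(1, 0, 2 * pi)
      clean[i, ] <- amp / 2 * (1 + sin(2 * pi * tt / period + phase))
    }
    total <- clean
    if (drift && p$drift_amplitude > 0) {
      # component amplitudes: the faster sinusoid is kept small (drift in
      # these recordings is dominated by slow bleaching-like trends)
      a120 <- 0.10 * p$drift_amplitude
      a300 <- 0.45 * p$drift_amplitude
      arw <- 0.45 * p$drift_amplitude
      ph1 <- stats::runif(nr, 0, 2 * pi)
      ph2 <- stats::runif(nr, 0, 2 * pi)
      # drift is slow: build it on a 2.5 s grid and interpolate linearly
      step <- max(1L, as.integer(round(2.5 * fr)))
      grid <- unique(c(seq(1L, nf, by = step), nf))
      ng <- length(grid)
      tg <- tt[grid]
      dg <- a120 * sin(outer(ph1, 2 * pi * tg / 120, "+")) +
        a300 * sin(outer(ph2, 2 * pi * tg / 300, "+"))
      # slow reflected random walk: wanders ~arw over the whole recording
      rw <- matrix(stats::rnorm(nr * ng, 0, 0.5 * arw / sqrt(ng)), nr, ng)
      rw <- t(apply(rw, 1L, cumsum))
      rw <- abs(((rw + arw) %% (4 * arw)) - 2 * arw) - arw
      dg <- dg + rw
      gi <- findInterval(seq_len(nf), grid, rightmost.closed = TRUE)
      gn <- pmin(gi + 1L, ng)
      gw <- (seq_len(nf) - grid[gi]) / pmax(grid[gn] - grid[gi], 1L)
      total <- total + dg[, gi, drop = FALSE] *
        rep(1 - gw, each = nr) + dg[, gn, drop = FALSE] * rep(gw, each = nr)
    }
    if (noise && p$noise_sd > 0) {
      total <- total + matrix(stats::rnorm(nr * nf, 0, p$noise_sd), nr, nf)
    }
    f_base <- stats::runif(nr, 80, 120)
    raw <- f_base * (1 + total / 100)
    structure(list(raw = raw, clean = clean, f_base = f_base,
                   frame_rate = fr, roles = culture$roles),
              class = "trace_set")
  })
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("Trace set: %d ROIs x %d frames (%.0f fps)\n",
              nrow(x$raw), ncol(x$raw), x$frame_rate))
  invisible(x)
}

#' Lay ROI footprints out on a square image
#'
#' Places `n_rois` disk footprints of the given radius on a jittered square
#' grid, keeping footprints disjoint and inside the image.
#'
#' @param n_rois Number of footprints.
#' @param image_size Image side length in pixels.
#' @param radius Disk radius in pixels (a radius of 3.5 px gives ~38-pixel
#'   somata, comfortably above the 10-pixel detection floor).
#' @param seed Integer seed for the jitter.
#' @return An object of class `roi_layout`: list with `centers` (n x 2,
#'   row/col), `footprints` (list of linear pixel indices, column-major) and
#'   `image_size`.
#' @export
make_roi_layout <- function(n_rois, image_size, radius = 3.5, seed = NULL) {
  ncell <- ceiling(sqrt(n_rois))
  cell <- floor(image_size / ncell)
  if (cell < 2 * radius + 3)
    stop("footprints do not fit: increase 'image_size' or decrease 'radius'")
  jit <- floor((cell - 2 * radius - 1) / 2)
  with_seed(seed, {
    slots <- utils::head(as.matrix(expand.grid(row = seq_len(ncell),
                                               col = seq_len(ncell))), n_rois)
    centers <- (slots - 0.5) * cell +
      matrix(stats::runif(2 * n_rois, -jit, jit), ncol = 2)
    centers <- round(centers)
    off <- as.matrix(expand.grid(dr = -ceiling(radius):ceiling(radius),
                                 dc = -ceiling(radius):ceiling(radius)))
    off <- off[off[, 1]^2 + off[, 2]^2 <= radius^2, , drop = FALSE]
    fp <- lapply(seq_len(n_rois), function(i) {
      rr <- centers[i, 1] + off[, 1]
      cc <- centers[i, 2] + off[, 2]
      keep <- rr >= 1 & rr <= image_size & cc >= 1 & cc <= image_size
      as.integer((cc[keep] - 1L) * image_size + rr[keep])
    })
    structure(list(centers = centers, footprints = fp,
                   image_size = as.integer(image_size)),
              class = "roi_layout")
  })
}

#' Render a fluorescence movie from traces
#'
#' Builds a frame stack in which every pixel holds a static background field
#' (a central illumination vignette plus fixed-pattern variation, as in real
#' epifluorescence images) plus per-frame Gaussian pixel noise, and pixels of
#' ROI `i` additionally hold `brightness * (1 + p_i(t) / 100)` with `p_i` the
#' ROI's total fluorescence excursion in % dF/F0. The time-average of such
#' a movie shows each soma above a spatially varying background, which is
#' what the percentile-normalizing ROI detector consumes.
#'
#' Rendering is deterministic given `seed`; `frame_idx` renders a subset of
#' frames (used to stream long movies in chunks without materialising the
#' full stack).
#'
#' @param traces A [render_traces()] result.
#' @param layout A [make_roi_layout()] with as many footprints as ROIs.
#' @param seed Integer seed for the pixel noise.
#' @param frame_idx Integer vector of frames to render (default: all).
#' @param background Mean background intensity (arbitrary units).
#' @param brightness Soma baseline intensity above zero signal.
#' @param px_noise_sd Gaussian pixel noise SD.
#' @param field_seed Seed of the static background field; keep it fixed
#'   across chunked renderings of the same movie.
#' @return An object of class `fluorescence_movie`: list with `data`
#'   (array `image_size` x `image_size` x frames) and `frame_rate`.
#' @export
render_movie <- function(traces, layout, seed = NULL, frame_idx = NULL,
                         background = 10, brightness = 150,
                         px_noise_sd = 1, field_seed = 1L) {
  if (length(layout$footprints) != nrow(traces$raw))
    stop("layout and trace set disagree on the number of ROIs")
  if (is.null(frame_idx)) frame_idx <- seq_len(ncol(traces$raw))
  n <- layout$image_size
  nf <- length(frame_idx)
  pct <- 100 * (traces$raw[, frame_idx, drop = FALSE] / traces$f_base - 1)
  field <- with_seed(field_seed, {
    rr <- matrix(seq_len(n), n, n)
    cc <- t(rr)
    # smooth, wide illumination vignette; per-pixel fixed-pattern noise is
    # deliberately absent so the time-averaged image is smooth, as for a
    # shot-noise-limited camera. The correlation length is kept much larger
    # than the detector's blur radius so background curvature cannot cross
    # the binarization threshold.
    vig <- exp(-((rr - n / 2)^2 + (cc - n / 2)^2) / (2 * (0.9 * n)^2))
    background * (0.4 + 0.8 * vig)
  })
  with_seed(seed, {
    arr <- array(stats::rnorm(n * n * nf, 0, px_noise_sd),
                 dim = c(n, n, nf))
    arr <- arr + as.vector(field)
    pix <- unlist(layout$footprints)
    roi_of_pix <- rep(seq_along(layout$footprints),
                      lengths(layout$footprints))
    vals <- brightness * (1 + pct[roi_of_pix, , drop = FALSE] / 100)
    lin <- outer(pix, (seq_len(nf) - 1L) * n * n, "+")
    arr[lin] <- arr[lin] + vals
    structure(list(data = arr, frame_rate = traces$frame_rate),
              class = "fluorescence_movie")
  })
}

#' @export
print.fluorescence_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Fluorescence movie: %d x %d px, %d frames (%.0f fps)\n",
              d[1], d[2], d[3], x$frame_rate))
  invisible(x)
}
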