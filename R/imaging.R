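#' Detect ROIs on the time-averaged image
#'
#' Segments somata from a fluorescence movie (or a pre-computed time-averaged
#' image) with the fixed pipeline: (1) normalize the average image between
#' its 20th and 30th intensity percentiles (affine rescale mapping the 20th
#' percentile to 0 and the 30th to 1: background lands near the unit
#' interval, somata far above it); (2) subtract
#' a Gaussian blur of width `blur_sigma` pixels (background estimate) from
#' the normalized image; (3) binarize the difference at `threshold`; (4) fill
#' holes; (5) morphologically open with a square structuring element of size
#' `opening_size`; (6) remove connected components with fewer than `min_px`
#' pixels. Components use 8-connectivity and are labelled in reading order of
#' their centroids (row, then column), so the output is deterministic.
#'
#' Percentiles use the linear-interpolation quantile definition
#' (`stats::quantile` type 7). A constant image yields an empty ROI set.
#'
#' @param x A `fluorescence_movie` or a numeric matrix (time-averaged image).
#' @param threshold Binarization threshold applied to the
#'   background-subtracted image.
#' @param blur_sigma Gaussian blur standard deviation in pixels.
#' @param opening_size Side of the square structuring element.
#' @param min_px Minimum component size in pixels.
#' @return An object of class `roi_set`: list with `pixels` (list of linear
#'   pixel indices per ROI, column-major), `centroids` (n x 2 row/col) and
#'   `dim` (image dimensions).
#' @export
detect_rois <- function(x, threshold = 0.08, blur_sigma = 7,
                        opening_size = 4, min_px = 10) {
  img <- if (inherits(x, "fluorescence_movie")) {
    rowMeans(x$data, dims = 2)
  } else {
    as.matrix(x)
  }
  empty <- structure(list(pixels = list(),
                          centroids = matrix(numeric(0), 0, 2,
                                             dimnames = list(NULL, c("row", "col"))),
                          dim = dim(img)),
                     class = "roi_set")
  q <- stats::quantile(img, c(0.20, 0.30), type = 7, names = FALSE)
  if (q[2] <= q[1]) return(empty)
  norm <- (img - q[1]) / (q[2] - q[1])

  ksz <- min(2L * ceiling(2.5 * blur_sigma) + 1L,
             (min(dim(img)) - 1L) %/% 2L * 2L + 1L)
  brush <- EBImage::makeBrush(ksz, shape = "gaussian", sigma = blur_sigma)
  # replicate-pad before filtering so the circular convolution cannot wrap
  # image content across opposite edges
  half <- (ksz - 1L) %/% 2L
  ri <- c(rep(1L, half), seq_len(nrow(norm)), rep(nrow(norm), half))
  ci <- c(rep(1L, half), seq_len(ncol(norm)), rep(ncol(norm), half))
  padded <- norm[ri, ci]
  bg <- EBImage::filter2(padded, brush)
  bg <- bg[half + seq_len(nrow(norm)), half + seq_len(ncol(norm))]
  enh <- norm - bg

  bin <- EBImage::fillHull(enh > threshold)
  kern <- matrix(1, opening_size, opening_size)
  opened <- EBImage::dilate(EBImage::erode(bin, kern), kern)

  lab <- label_components8(opened > 0)
  if (max(lab) == 0L) return(empty)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  if (!length(keep)) return(empty)

  idx <- which(lab > 0L & matrix(lab %in% keep, nrow(lab)))
  labs <- lab[idx]
  rows <- (idx - 1L) %% nrow(img) + 1L
  cols <- (idx - 1L) %/% nrow(img) + 1L
  cen_r <- tapply(rows, labs, mean)
  cen_c <- tapply(cols, labs, mean)
  ord <- order(cen_r, cen_c)
  pix <- split(as.integer(idx), labs)[ord]
  names(pix) <- NULL
  structure(list(pixels = pix,
                 centroids = cbind(row = as.numeric(cen_r[ord]),
                                   col = as.numeric(cen_c[ord])),
                 dim = dim(img)),
            class = "roi_set")
}

# 8-connected component labelling: EBImage::bwlabel (4-connected) followed by
# union of labels that touch diagonally.
label_components8 <- function(bin) {
  lab <- EBImage::bwlabel(bin)
  lab <- matrix(as.integer(round(lab)), nrow(bin))
  nmax <- max(lab)
  if (nmax <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- NULL
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1L), if (sh[2] > 0) seq_len(nc - 1L) else 2:nc]
    b <- lab[2:nr, if (sh[2] > 0) 2:nc else seq_len(nc - 1L)]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  if (is.null(pairs)) return(lab)
  g <- igraph::graph_from_edgelist(unique(pairs), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nmax - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[lab > 0L] <- comp[lab[lab > 0L]]
  lab
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("ROI set: %d ROIs on a %d x %d image\n",
              length(x$pixels), x$dim[1], x$dim[2]))
  invisible(x)
}

#' Label image of an ROI set
#' @param rois A [detect_rois()] result.
#' @return Integer matrix with 0 background and ROI labels 1..n.
#' @export
roi_label_image <- function(rois) {
  lab <- matrix(0L, rois$dim[1], rois$dim[2])
  for (i in seq_along(rois$pixels)) lab[rois$pixels[[i]]] <- i
  lab
}

#' Extract raw fluorescence traces for an ROI set
#'
#' The trace of ROI `i` at frame `t` is the spatial mean of its pixels.
#'
#' @param movie A `fluorescence_movie`.
#' @param rois A [detect_rois()] result (pixel indices must lie inside the
#'   movie's frames).
#' @return Numeric matrix, one row per ROI, one column per frame.
#' @export
extract_traces <- function(movie, rois) {
  d <- dim(movie$data)
  if (!length(rois$pixels))
    return(matrix(numeric(0), 0, d[3]))
  npx <- d[1] * d[2]
  if (any(unlist(rois$pixels) > npx))
    stop("ROI pixels outside the movie frame")
  flat <- matrix(movie$data, npx, d[3])
  t(vapply(rois$pixels, function(px)
    colMeans(flat[px, , drop = FALSE]), numeric(d[3])))
}

#' Baseline-correct and normalize fluorescence traces
#'
#' Per trace: (1) smooth with a centred square (boxcar) sliding window of
#' `boxcar` frames; (2) partition time into blocks of `block_s` seconds; in
#' each block take as reference point the sample whose value is closest to
#' the block's `block_q` lower fluorescence percentile (linear-interpolation
#' quantile); a trailing partial block contributes its own reference point if
#' at least 10 s long and is merged into the previous block otherwise;
#' (3) fit a smoothing spline through the reference points, giving the
#' baseline `F0(t)`; (4) normalize to `r = 100 * (F - F0) / F0` % dF/F0.
#'
#' The spline stiffness is set through its equivalent degrees of freedom,
#' about 1.35 per 100 s of recording, so the fitted baseline follows slow
#' drift but not calcium transients. Traces whose fitted baseline is not
#' strictly positive are flagged invalid (`valid = FALSE`) and carry `NA`
#' normalized values; downstream stages skip them.
#'
#' @param f Raw trace matrix (ROI x frame) or an [extract_traces()] result.
#' @param frame_rate Frames per second.
#' @param block_s Baseline block length in seconds.
#' @param block_q Lower-percentile reference level within each block.
#' @param boxcar Smoothing window width in frames.
#' @param spline_df_per_100s Spline flexibility per 100 s of recording.
#' @return An object of class `trace_matrix`: list with `F` (input), `F_smooth`,
#'   `F0`, `r` (% dF/F0), `frame_rate` and `valid`.
#' @export
normalize_traces <- function(f, frame_rate, block_s = 50, block_q = 0.10,
                             boxcar = 5, spline_df_per_100s = 1.35) {
  f <- as.matrix(f)
  nf <- ncol(f)
  nr <- nrow(f)
  if (nf < 2) stop("need at least one block of data")
  block_len <- max(1L, as.integer(round(block_s * frame_rate)))
  starts <- seq(1L, nf, by = block_len)
  ends <- pmin(starts + block_len - 1L, nf)
  # trailing partial block: keep if >= 10 s, else merge into previous
  if (length(starts) > 1L) {
    last_len <- ends[length(ends)] - starts[length(starts)] + 1L
    if (last_len < 10 * frame_rate) {
      ends[length(ends) - 1L] <- nf
      starts <- starts[-length(starts)]
      ends <- ends[-length(ends)]
    }
  }
  nb <- length(starts)
  df_target <- max(2, min(nb, 2 + spline_df_per_100s * nf / frame_rate / 100))

  f_smooth <- boxcar_smooth_rows(f, boxcar)

  ## per-block reference points (value closest to the block's lower
  ## percentile), computed for all traces at once via row sorting
  ref_t <- matrix(NA_integer_, nr, nb)
  ref_v <- matrix(NA_real_, nr, nb)
  for (b in seq_len(nb)) {
    bl <- f_smooth[, starts[b]:ends[b], drop = FALSE]
    len <- ncol(bl)
    h <- (len - 1) * block_q + 1
    k <- floor(h); g <- h - k
    k2 <- min(k + 1L, len)
    for (i in seq_len(nr)) {
      v <- bl[i, ]
      os <- sort(v, partial = c(k, k2))
      qv <- (1 - g) * os[k] + g * os[k2]
      j <- which.min(abs(v - qv))
      ref_t[i, b] <- starts[b] + j - 1L
      ref_v[i, b] <- v[j]
    }
  }

  ## smoothing spline through the reference points, evaluated on a coarse
  ## grid (the baseline is slow by construction) and linearly interpolated
  grid <- unique(c(seq(1L, nf, by = 25L), nf))
  gi <- findInterval(seq_len(nf), grid, rightmost.closed = TRUE)
  gw <- (seq_len(nf) - grid[gi]) /
    pmax(grid[pmin(gi + 1L, length(grid))] - grid[gi], 1L)
  gn <- pmin(gi + 1L, length(grid))
  f0 <- matrix(NA_real_, nr, nf)
  r <- matrix(NA_real_, nr, nf)
  valid <- rep(TRUE, nr)
  for (i in seq_len(nr)) {
    # evaluate within the reference-point span and extend constantly past
    # it: spline extrapolation at the recording edges is unconstrained and
    # would distort the first/last seconds of baseline
    xg <- pmin(pmax(grid, ref_t[i, 1L]), ref_t[i, nb])
    vg <- if (nb >= 4L) {
      sp <- stats::smooth.spline(ref_t[i, ], ref_v[i, ], df = df_target)
      stats::predict(sp, xg)$y
    } else if (nb >= 2L) {
      stats::approx(ref_t[i, ], ref_v[i, ], xout = xg, rule = 2,
                    ties = "ordered")$y
    } else {
      rep(ref_v[i, 1L], length(grid))
    }
    base <- vg[gi] * (1 - gw) + vg[gn] * gw
    f0[i, ] <- base
    if (any(base <= 0)) {
      valid[i] <- FALSE
      next
    }
    r[i, ] <- 100 * (f_smooth[i, ] - base) / base
  }
  structure(list(F = f, F_smooth = f_smooth, F0 = f0, r = r,
                 frame_rate = frame_rate, valid = valid),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("Trace matrix: %d ROIs x %d frames (%.0f fps), %d invalid\n",
              nrow(x$r), ncol(x$r), x$frame_rate, sum(!x$valid)))
  invisible(x)
}
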