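# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded generator calls do not perturb the caller's
#' random stream. A `NULL` seed evaluates the code with the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# robust per-sample noise scale from first differences (transient-insensitive);
# long traces are subsampled evenly, which leaves the estimate unchanged for
# stationary noise at a fraction of the cost
robust_noise_sd <- function(x, max_samples = 2000L) {
  n <- length(x)
  if (n < 3L) return(0)
  if (n - 1L > max_samples) {
    at <- as.integer(seq.int(1L, n - 1L, length.out = max_samples))
    d <- x[at + 1L] - x[at]
  } else {
    d <- diff(x)
  }
  stats::mad(d, constant = 1.4826) / sqrt(2)
}

# truncated centred boxcar applied to every row of a matrix at once
boxcar_smooth_rows <- function(x, width) {
  if (width <= 1L) return(x)
  half <- (width - 1L) %/% 2L
  nf <- ncol(x)
  acc <- x
  cnt <- rep(1, nf)
  for (d in seq_len(half)) {
    acc[, (1 + d):nf] <- acc[, (1 + d):nf] + x[, 1:(nf - d), drop = FALSE]
    acc[, 1:(nf - d)] <- acc[, 1:(nf - d)] + x[, (1 + d):nf, drop = FALSE]
    cnt[(1 + d):nf] <- cnt[(1 + d):nf] + 1
    cnt[1:(nf - d)] <- cnt[1:(nf - d)] + 1
  }
  sweep(acc, 2L, cnt, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
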