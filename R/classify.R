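#' Moment-based features of normalized traces
#'
#' Computes the fixed 8-feature vector used by the trace classifier: mean,
#' variance, skewness, excess kurtosis, number of upward crossings of twice
#' the robust noise SD, fraction of time spent above that threshold, the
#' fraction of spectral power below 0.1 Hz (excluding DC; computed on the
#' trace block-averaged to ~2 Hz, which leaves sub-0.1 Hz content untouched),
#' and the maximum dF/F0 value. Zero-variance traces get skewness and
#' kurtosis 0 by convention. The feature schema is versioned through its
#' column names; classifiers refuse feature matrices with a different schema.
#'
#' @param tm A [normalize_traces()] result, or a numeric ROI x frame matrix
#'   of normalized traces.
#' @param frame_rate Frames per second (taken from `tm` when available).
#' @return Numeric matrix, one row per trace, with named feature columns.
#' @export
featurize_traces <- function(tm, frame_rate = NULL) {
  if (inherits(tm, "trace_matrix")) {
    x <- tm$r
    frame_rate <- tm$frame_rate
  } else {
    x <- as.matrix(tm)
    if (is.null(frame_rate)) stop("'frame_rate' required for a bare matrix")
  }
  nf <- ncol(x)
  out <- matrix(NA_real_, nrow(x), 8,
                dimnames = list(NULL, trace_feature_names()))
  # decimate to ~2 Hz for the low-frequency power feature
  dec <- max(1L, floor(frame_rate / 2))
  nd <- nf %/% dec
  freqs <- (seq_len(nd) - 1) * (frame_rate / dec) / nd
  half <- which(freqs > 0 & freqs <= frame_rate / dec / 2)
  lf <- freqs[half] < 0.1
  # moments for all traces at once
  ok <- !apply(x, 1L, anyNA)
  m <- rowMeans(x)
  cent <- x - m
  s2 <- rowSums(cent^2) / (nf - 1)
  mc <- rowMeans(cent^2)
  sk <- ifelse(s2 > 0, rowMeans(cent^3) / mc^1.5, 0)
  ku <- ifelse(s2 > 0, rowMeans(cent^4) / mc^2 - 3, 0)
  for (i in which(ok)) {
    v <- x[i, ]
    sig <- robust_noise_sd(v)
    thr <- 2 * sig
    above <- sig > 0 & v > thr
    crossings <- if (sig > 0) sum(diff(above) == 1L) else 0L
    vd <- colMeans(matrix(cent[i, seq_len(nd * dec)], dec))
    pw <- Mod(stats::fft(vd))^2
    tot <- sum(pw[half])
    lfp <- if (tot > 0) sum(pw[half][lf]) / tot else 0
    out[i, ] <- c(m[i], s2[i], sk[i], ku[i], crossings, mean(above), lfp,
                  max(v))
  }
  out
}

trace_feature_names <- function() {
  c("mean", "variance", "skewness", "kurtosis_excess", "crossings",
    "frac_above", "lf_power", "max")
}

#' Train the neuron/glia/silent trace classifier
#'
#' Multi-class adaptive boosting (SAMME) over shallow `rpart` decision trees
#' (depth-1 stumps by default) on the [featurize_traces()] schema. The small
#' feature space makes a short boosted ensemble sufficient; the classifier
#' supports iterative refinement by simply retraining on an amended label
#' set.
#'
#' @param features Feature matrix from [featurize_traces()].
#' @param labels Character/factor labels, one of `"neuron"`, `"glia"`,
#'   `"silent"` (any >= 2 distinct classes are accepted).
#' @param n_rounds Number of boosting rounds.
#' @param maxdepth Depth of the base learners.
#' @param seed Integer seed (tie-breaking inside the tree fits).
#' @return An object of class `trace_classifier`.
#' @export
train_trace_classifier <- function(features, labels, n_rounds = 50,
                                   maxdepth = 1, seed = 1L) {
  features <- as.matrix(features)
  if (!identical(colnames(features), trace_feature_names()))
    stop("feature schema mismatch: expected featurize_traces() columns")
  y <- factor(as.character(labels))
  if (nlevels(y) < 2) stop("training labels must contain at least 2 classes")
  if (anyNA(features)) stop("features contain NA (invalid traces?)")
  k <- nlevels(y)
  n <- nrow(features)
  df <- data.frame(.y = y, features, check.names = FALSE)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, minsplit = 2, cp = 0,
                               xval = 0)
  with_seed(seed, {
    w <- rep(1 / n, n)
    stumps <- list()
    alphas <- numeric(0)
    for (r in seq_len(n_rounds)) {
      fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                          control = ctrl)
      pred <- stats::predict(fit, df, type = "class")
      miss <- pred != y
      err <- sum(w[miss]) / sum(w)
      if (err >= 1 - 1 / k) break          # worse than chance: stop
      err <- max(err, 1e-10)
      alpha <- log((1 - err) / err) + log(k - 1)
      stumps[[length(stumps) + 1L]] <- fit
      alphas <- c(alphas, alpha)
      if (sum(miss) == 0L) break           # separable: one learner suffices
      w <- w * exp(alpha * miss)
      w <- w / sum(w)
    }
    if (!length(stumps)) stop("boosting failed to fit any base learner")
    structure(list(stumps = stumps, alphas = alphas, classes = levels(y),
                   schema = trace_feature_names()),
              class = "trace_classifier")
  })
}

#' @export
print.trace_classifier <- function(x, ...) {
  cat(sprintf("Boosted trace classifier: %d rounds, classes: %s\n",
              length(x$stumps), paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Classify traces with a trained ensemble
#'
#' @param model A [train_trace_classifier()] model.
#' @param features Feature matrix with the model's schema. Rows containing
#'   `NA` (invalid traces) are labelled `"silent"` with zero confidence.
#' @return A data frame with `label` and one probability column per class
#'   (normalized ensemble votes, exposed for audit).
#' @export
classify_traces <- function(model, features) {
  if (!inherits(model, "trace_classifier")) stop("not a trace_classifier")
  features <- as.matrix(features)
  if (!identical(colnames(features), model$schema))
    stop("feature schema mismatch")
  n <- nrow(features)
  k <- length(model$classes)
  votes <- matrix(0, n, k, dimnames = list(NULL, model$classes))
  ok <- !apply(features, 1L, anyNA)
  if (any(ok)) {
    df <- data.frame(features[ok, , drop = FALSE], check.names = FALSE)
    for (j in seq_along(model$stumps)) {
      pred <- as.character(stats::predict(model$stumps[[j]], df,
                                          type = "class"))
      votes[cbind(which(ok), match(pred, model$classes))] <-
        votes[cbind(which(ok), match(pred, model$classes))] + model$alphas[j]
    }
  }
  lab <- rep("silent", n)
  tot <- rowSums(votes)
  lab[ok] <- model$classes[max.col(votes[ok, , drop = FALSE],
                                   ties.method = "first")]
  probs <- votes / ifelse(tot > 0, tot, 1)
  out <- data.frame(label = lab, check.names = FALSE)
  out <- cbind(out, as.data.frame(probs))
  out
}

# package-level cache for the default classifier
.calnet_env <- new.env(parent = emptyenv())

#' Default pre-trained trace classifier
#'
#' Returns (building and caching on first use) a classifier trained on
#' generator-rendered traces of the three classes, so the pipeline runs
#' end-to-end without manual labelling. Training draws `n_per_class` traces
#' per class over a range of spike rates, wave amplitudes and noise levels.
#' Manually curated labels always override: retrain with
#' [train_trace_classifier()] on an amended label set.
#'
#' @param n_per_class Training traces per class.
#' @param seed Integer seed.
#' @return A `trace_classifier`.
#' @export
default_trace_classifier <- function(n_per_class = 150, seed = 20L) {
  key <- sprintf("clf_%d_%d", n_per_class, seed)
  if (!is.null(.calnet_env[[key]])) return(.calnet_env[[key]])
  tr <- with_seed(seed, classifier_training_set(n_per_class))
  clf <- train_trace_classifier(tr$features, tr$labels, seed = seed)
  .calnet_env[[key]] <- clf
  clf
}

# Renders single-ROI raw traces of each class (recording-length, 600 s at
# 20 fps) with baseline drift and noise spanning a range of amplitudes and
# rates, then pushes them through the same normalization the pipeline
# applies, so the training features live in the same space as pipeline
# features. The neuron rate range reaches down to ~3 transients per
# recording so that sparsely firing neurons are still separated from
# silent ROIs.
classifier_training_set <- function(n_per_class) {
  fr <- 20; dur <- 600; nf <- fr * dur
  decay <- exp(-1 / (3 * fr))
  tt <- (seq_len(nf) - 1) / fr
  n <- 3L * n_per_class
  labels <- rep(c("neuron", "glia", "silent"), each = n_per_class)
  raw <- matrix(0, n, nf)
  for (i in seq_len(n)) {
    sig <- switch(labels[i],
      neuron = {
        rate <- exp(stats::runif(1, log(0.005), log(1.2)))
        x <- numeric(nf)
        x[stats::runif(nf) < rate / fr] <- stats::runif(1, 0.7, 1.3)
        as.numeric(stats::filter(x, decay, method = "recursive"))
      },
      glia = {
        amp <- stats::runif(1, 5, 20)
        per <- stats::runif(1, 25, 35)
        amp / 2 * (1 + sin(2 * pi * tt / per + stats::runif(1, 0, 2 * pi)))
      },
      silent = numeric(nf))
    da <- stats::runif(1, 0.5, 3)    # total drift amplitude, % dF/F0
    rw <- cumsum(stats::rnorm(nf, 0, 0.5 * 0.45 * da / sqrt(nf)))
    a_rw <- 0.45 * da
    rw <- abs(((rw + a_rw) %% (4 * a_rw)) - 2 * a_rw) - a_rw
    dr <- 0.10 * da * sin(2 * pi * tt / 120 + stats::runif(1, 0, 2 * pi)) +
      0.45 * da * sin(2 * pi * tt / 300 + stats::runif(1, 0, 2 * pi)) + rw
    noise_sd <- stats::runif(1, 0.05, 0.4)
    raw[i, ] <- 100 * (1 + (sig + dr + stats::rnorm(nf, 0, noise_sd)) / 100)
  }
  tm <- normalize_traces(raw, frame_rate = fr)
  list(features = featurize_traces(tm), labels = labels)
}
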