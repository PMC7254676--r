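#' Quartile-criterion (Tukey fence) outlier exclusion
#'
#' Excludes values outside `[Q1 - k * IQR, Q3 + k * IQR]`, with quartiles
#' computed by the linear-interpolation quantile definition. Groups with
#' fewer than four values are returned unchanged with a warning. Exclusion
#' is idempotent: fences are computed once on the input sample.
#'
#' @param x Numeric vector (one group's samples).
#' @param k Fence multiplier.
#' @return A list with `values` (kept), `excluded`, and `excluded_idx`.
#' @export
remove_outliers_quartile <- function(x, k = 1.5) {
  x <- as.numeric(x)
  ok <- !is.na(x)
  if (sum(ok) < 4L) {
    warning("fewer than 4 values: no outlier exclusion performed")
    return(list(values = x[ok], excluded = numeric(0),
                excluded_idx = integer(0)))
  }
  q <- stats::quantile(x[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  out <- ok & (x < lo | x > hi)
  list(values = x[ok & !out], excluded = x[out], excluded_idx = which(out))
}

#' Unpaired two-sample Student's t test with group summaries
#'
#' Classic equal-variance two-sample t test between two groups of culture
#' observables (outliers are assumed to have been handled beforehand, e.g.
#' with [remove_outliers_quartile()]). Degenerate samples with zero pooled
#' variance and equal means report `t = 0, p = 1`.
#'
#' @param a,b Numeric samples.
#' @param var_equal Use the pooled-variance (Student) statistic.
#' @return An object of class `comparison_result`: list with `test`,
#'   `statistic`, `df`, `p`, and per-group `mean`, `sem`, `sd`, `n`.
#' @export
compare_groups_ttest <- function(a, b, var_equal = TRUE) {
  a <- as.numeric(a[!is.na(a)])
  b <- as.numeric(b[!is.na(b)])
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 values per group")
  grp <- function(x) c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
                       sd = stats::sd(x), n = length(x))
  res <- tryCatch(
    stats::t.test(a, b, var.equal = var_equal),
    error = function(e) NULL)
  if (is.null(res)) {
    # constant data: equal means are evidence of no difference
    stat <- if (isTRUE(all.equal(mean(a), mean(b)))) 0 else Inf
    p <- if (stat == 0) 1 else 0
    df <- length(a) + length(b) - 2
  } else {
    stat <- unname(res$statistic)
    p <- res$p.value
    df <- unname(res$parameter)
  }
  structure(list(test = if (var_equal) "Student t (unpaired)" else "Welch t",
                 statistic = stat, df = df, p = p,
                 groups = rbind(a = grp(a), b = grp(b))),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$test,
              x$statistic, paste(signif(x$df, 4), collapse = ", "), x$p))
  if (!is.null(x$groups)) print(round(x$groups, 4))
  if (!is.null(x$effects)) {
    cat("Effects:\n"); print(x$effects)
  }
  if (!is.null(x$posthoc)) {
    cat("Bonferroni post hoc:\n"); print(x$posthoc)
  }
  invisible(x)
}

#' Mixed-design (split-plot) ANOVA with Bonferroni post hoc tests
#'
#' Two-way mixed-design ANOVA for a repeated-measures design: one
#' between-subject factor (e.g. genotype) and one within-subject factor
#' (e.g. treatment phase), each culture measured in both phases. F statistics
#' come from the classical split-plot decomposition
#' (`aov(dv ~ between * within + Error(subject / within))`), matching the
#' `F(df1, df2)` reporting style of culture studies. Cultures missing a phase
#' are excluded listwise with a warning.
#'
#' Two Bonferroni-corrected post hoc families are computed and labelled:
#' the within-factor effect inside each between-group (paired t tests,
#' corrected by the number of groups) and the between-factor effect inside
#' each phase (unpaired t tests, corrected by the number of phases).
#'
#' @param data Data frame with one row per culture per phase.
#' @param dv Name of the dependent-variable column.
#' @param between,within,subject Names of the factor columns.
#' @return A `comparison_result` with an `effects` table (F, df, p per
#'   effect) and a `posthoc` table.
#' @export
mixed_anova_posthoc <- function(data, dv, between, within, subject) {
  d <- data.frame(y = data[[dv]],
                  g = factor(data[[between]]),
                  p = factor(data[[within]]),
                  s = factor(data[[subject]]))
  d <- d[!is.na(d$y), , drop = FALSE]
  n_phase <- nlevels(d$p)
  complete <- names(which(tapply(d$p, d$s, function(x)
    length(unique(x))) == n_phase))
  if (length(complete) < length(unique(d$s)))
    warning(sprintf("%d subject(s) missing a phase: excluded listwise",
                    length(unique(d$s)) - length(complete)))
  d <- d[d$s %in% complete, , drop = FALSE]
  d$s <- droplevels(d$s)
  if (nlevels(d$g) < 2 || nlevels(d$p) < 2)
    stop("need >= 2 levels of both factors after exclusion")

  fit <- stats::aov(y ~ g * p + Error(s / p), data = d)
  sm <- summary(fit)
  tab_b <- sm[["Error: s"]][[1]]
  tab_w <- sm[["Error: s:p"]][[1]]
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    err <- nrow(tab) # residual row is last
    f <- tab[i, "F value"]
    p <- tab[i, "Pr(>F)"]
    # degenerate stratum (effect and residual sums of squares both zero up
    # to floating noise): no evidence of an effect
    if ((!is.finite(f) || tab[err, "Sum Sq"] < 1e-12) &&
        tab[i, "Sum Sq"] < 1e-12) {
      f <- 0
      p <- 1
    }
    c(F = f, df1 = tab[i, "Df"], df2 = tab[err, "Df"], p = p)
  }
  effects <- rbind(between = pick(tab_b, "g"),
                   within = pick(tab_w, "p"),
                   interaction = pick(tab_w, "g:p"))
  rownames(effects) <- c(between, within,
                         paste0(between, ":", within))

  ## post hoc families
  ph <- list()
  m_a <- nlevels(d$g)
  for (gl in levels(d$g)) {
    sub <- d[d$g == gl, ]
    wide <- stats::reshape(sub[, c("s", "p", "y")], idvar = "s",
                           timevar = "p", direction = "wide")
    ys <- wide[, -1, drop = FALSE]
    if (ncol(ys) == 2 && nrow(ys) >= 2) {
      tt <- stats::t.test(ys[[1]], ys[[2]], paired = TRUE)
      ph[[length(ph) + 1L]] <- data.frame(
        family = sprintf("%s within %s", within, between),
        comparison = sprintf("%s: %s vs %s", gl, levels(d$p)[1],
                             levels(d$p)[2]),
        p_raw = tt$p.value, p_bonferroni = min(1, m_a * tt$p.value))
    }
  }
  m_b <- nlevels(d$p)
  for (pl in levels(d$p)) {
    sub <- d[d$p == pl, ]
    ga <- sub$y[sub$g == levels(d$g)[1]]
    gb <- sub$y[sub$g == levels(d$g)[2]]
    if (length(ga) >= 2 && length(gb) >= 2) {
      tt <- stats::t.test(ga, gb, var.equal = TRUE)
      ph[[length(ph) + 1L]] <- data.frame(
        family = sprintf("%s within %s", between, within),
        comparison = sprintf("%s: %s vs %s", pl, levels(d$g)[1],
                             levels(d$g)[2]),
        p_raw = tt$p.value, p_bonferroni = min(1, m_b * tt$p.value))
    }
  }
  structure(list(test = "mixed-design ANOVA", statistic = effects[, "F"],
                 df = effects[, c("df1", "df2")], p = effects[, "p"],
                 effects = as.data.frame(effects),
                 posthoc = do.call(rbind, ph),
                 n_subjects = nlevels(d$s)),
            class = "comparison_result")
}

#' Mean, SEM and SD summary per group
#' @param x Numeric vector.
#' @return Named vector with `mean`, `sem`, `sd`, `n`.
#' @export
group_summary <- function(x) {
  x <- x[!is.na(x)]
  c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
    sd = stats::sd(x), n = length(x))
}
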