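# Group statistics: Tukey-fence outliers, Student's t, mixed-design ANOVA.

# hand-computed split-plot sums-of-squares decomposition (the oracle)
mixed_anova_oracle <- function(d) {
  # d: columns y, g (between), p (within), s (subject); balanced complete
  gm <- mean(d$y)
  n_s <- length(unique(d$s))
  n_p <- length(unique(d$p))
  subj_means <- tapply(d$y, d$s, mean)
  subj_group <- tapply(as.character(d$g), d$s, `[`, 1)
  g_means <- tapply(d$y, d$g, mean)
  p_means <- tapply(d$y, d$p, mean)
  gp_means <- tapply(d$y, list(d$g, d$p), mean)
  n_per_g <- table(subj_group)

  ss_g <- n_p * sum(n_per_g * (tapply(subj_means, subj_group, mean) - gm)^2)
  ss_subj <- n_p * sum((subj_means - g_means[subj_group])^2)
  ss_p <- n_s * sum((p_means - gm)^2)
  ss_gp <- 0
  for (g in rownames(gp_means)) for (p in colnames(gp_means))
    ss_gp <- ss_gp + n_per_g[g] *
      (gp_means[g, p] - g_means[g] - p_means[p] + gm)^2
  ss_tot <- sum((d$y - gm)^2)
  ss_err <- ss_tot - ss_g - ss_subj - ss_p - ss_gp

  df_g <- length(g_means) - 1
  df_subj <- n_s - length(g_means)
  df_p <- n_p - 1
  df_gp <- df_g * df_p
  df_err <- df_subj * df_p
  c(F_g = unname((ss_g / df_g) / (ss_subj / df_subj)),
    F_p = unname((ss_p / df_p) / (ss_err / df_err)),
    F_gp = unname((ss_gp / df_gp) / (ss_err / df_err)))
}

make_design <- function(n_per_group, effect_g = 0, effect_p = 0,
                        effect_gp = 0, subj_sd = 1, noise_sd = 1, seed = 1) {
  set.seed(seed)
  subs <- paste0("s", seq_len(2 * n_per_group))
  g <- rep(c("WT", "HD"), each = n_per_group)
  b <- rnorm(2 * n_per_group, 0, subj_sd)
  rows <- list()
  for (i in seq_along(subs)) for (p in c("basal", "treated")) {
    y <- b[i] + effect_g * (g[i] == "HD") + effect_p * (p == "treated") +
      effect_gp * (g[i] == "HD") * (p == "treated") + rnorm(1, 0, noise_sd)
    rows[[length(rows) + 1L]] <- data.frame(culture = subs[i],
                                            genotype = g[i], phase = p,
                                            y = y)
  }
  do.call(rbind, rows)
}

test_that("values within the Tukey fences are never excluded", {
  out <- remove_outliers_quartile(1:10)
  expect_length(out$excluded, 0)
  expect_equal(out$values, as.numeric(1:10))
})

test_that("a gross outlier beyond the 1.5 IQR fence is excluded", {
  x <- c(1:10, 100)
  # by hand (type-7 quantiles of 11 values): Q1 = 3.5, Q3 = 8.5, IQR = 5,
  # fences [-4, 16]
  out <- remove_outliers_quartile(x)
  expect_equal(out$excluded, 100)
  expect_equal(out$values, as.numeric(1:10))
  expect_equal(out$excluded_idx, 11L)
})

test_that("all-equal samples are untouched and exclusion is idempotent", {
  out <- remove_outliers_quartile(rep(7, 8))
  expect_length(out$excluded, 0)
  set.seed(2)
  x <- c(rnorm(20), 50)
  once <- remove_outliers_quartile(x)
  twice <- remove_outliers_quartile(once$values)
  expect_equal(sort(twice$values), sort(once$values))
})

test_that("tiny groups trigger a warning and no exclusion", {
  expect_warning(out <- remove_outliers_quartile(c(1, 2, 100)), "fewer than 4")
  expect_length(out$excluded, 0)
})

test_that("identical groups give t = 0 and p = 1", {
  r <- compare_groups_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p, 1)
  r2 <- compare_groups_ttest(rep(4, 5), rep(4, 5))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p, 1)
})

test_that("the t statistic matches the pooled-variance closed form", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  r <- compare_groups_ttest(a, b)
  sp <- sqrt(((2) * var(a) + (2) * var(b)) / 4)
  t_ref <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(r$statistic, t_ref, tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(t_ref, 4), tolerance = 1e-12)
  expect_equal(unname(r$groups["a", c("mean", "sd", "n")]), c(2, 1, 3))
  expect_equal(unname(r$groups["a", "sem"]), 1 / sqrt(3))
})

test_that("the t test holds its nominal type-I error rate", {
  set.seed(123)
  rejections <- 0
  for (i in 1:10000) {
    if (stats::t.test(rnorm(20), rnorm(20), var.equal = TRUE)$p.value < 0.05)
      rejections <- rejections + 1
  }
  rate <- rejections / 10000
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("mixed ANOVA F values match the hand-computed decomposition", {
  d <- make_design(6, effect_g = 1, effect_p = 1.5, effect_gp = 0.8,
                   seed = 42)
  r <- mixed_anova_posthoc(d, "y", "genotype", "phase", "culture")
  ref <- mixed_anova_oracle(data.frame(y = d$y, g = d$genotype, p = d$phase,
                                       s = d$culture))
  expect_equal(unname(r$effects["genotype", "F"]), unname(ref["F_g"]),
               tolerance = 1e-8)
  expect_equal(unname(r$effects["phase", "F"]), unname(ref["F_p"]),
               tolerance = 1e-8)
  expect_equal(unname(r$effects["genotype:phase", "F"]), unname(ref["F_gp"]),
               tolerance = 1e-8)
  expect_equal(unname(r$effects["genotype", "df2"]), 10)
  expect_equal(unname(r$effects["phase", "df2"]), 10)
})

test_that("no effects anywhere gives F near 0 and p near 1", {
  # subjects differ, but group and phase means are identical by construction
  subs <- paste0("s", 1:8)
  d <- data.frame(culture = rep(subs, each = 2),
                  genotype = rep(c("WT", "HD"), each = 8),
                  phase = rep(c("basal", "treated"), 8),
                  y = rep(c(1, 2, 3, 4), each = 4))
  r <- mixed_anova_posthoc(d, "y", "genotype", "phase", "culture")
  expect_lt(unname(r$effects["phase", "F"]), 1e-20)
  expect_gt(unname(r$effects["phase", "p"]), 0.99)
  expect_gt(unname(r$effects["genotype:phase", "p"]), 0.99)
})

test_that("a pure treatment effect is detected and no spurious interaction appears", {
  hit_p <- 0; null_gp <- 0
  n_rep <- 500
  for (i in seq_len(n_rep)) {
    d <- make_design(8, effect_p = 1.5, noise_sd = 1, subj_sd = 1,
                     seed = 2000 + i)
    r <- mixed_anova_posthoc(d, "y", "genotype", "phase", "culture")
    if (r$effects["phase", "p"] < 0.05) hit_p <- hit_p + 1
    if (r$effects["genotype:phase", "p"] > 0.05) null_gp <- null_gp + 1
  }
  expect_gte(hit_p / n_rep, 0.9)
  expect_gte(null_gp / n_rep, 0.9)
})

test_that("cultures missing a phase are excluded listwise with a warning", {
  d <- make_design(5, seed = 3)
  d <- d[-1, ]  # s1 loses its basal measurement
  expect_warning(r <- mixed_anova_posthoc(d, "y", "genotype", "phase",
                                          "culture"), "listwise")
  expect_equal(r$n_subjects, 9)
})

test_that("Bonferroni adjustment is min(1, m * p) and monotone", {
  d <- make_design(6, effect_p = 2, seed = 8)
  r <- mixed_anova_posthoc(d, "y", "genotype", "phase", "culture")
  ph <- r$posthoc
  fam_a <- ph[ph$family == "phase within genotype", ]
  expect_equal(fam_a$p_bonferroni, pmin(1, 2 * fam_a$p_raw))
  fam_b <- ph[ph$family == "genotype within phase", ]
  expect_equal(fam_b$p_bonferroni, pmin(1, 2 * fam_b$p_raw))
  expect_true(all(ph$p_bonferroni >= ph$p_raw - 1e-15))
})

test_that("group summaries match the direct formulas", {
  set.seed(4)
  x <- rnorm(12)
  g <- group_summary(x)
  expect_equal(unname(g["mean"]), mean(x))
  expect_equal(unname(g["sd"]), sd(x))
  expect_equal(unname(g["sem"]), sd(x) / sqrt(12))
  expect_equal(unname(g["n"]), 12)
})
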