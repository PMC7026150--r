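test_that("welch_t matches base t.test and the summary route exactly", {
  set.seed(101)
  for (k in 1:5) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    mine <- welch_t(x, y)
    oracle <- t.test(x, y, var.equal = FALSE)
    expect_equal(mine$statistic, unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(oracle$parameter), tolerance = 1e-12)
    expect_equal(mine$p, oracle$p.value, tolerance = 1e-12)
    via_summaries <- welch_from_summaries(summarize_sample(x),
                                          summarize_sample(y))
    expect_equal(via_summaries$statistic, mine$statistic, tolerance = 1e-12)
    expect_equal(via_summaries$df, mine$df, tolerance = 1e-12)
  }
})

test_that("welch edge cases: equal means, copied sample, degenerate variance", {
  s1 <- group_summary(30, 5, 2, "mean_sd")
  s2 <- group_summary(50, 5, 3, "mean_sd")
  r <- welch_from_summaries(s1, s2)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  x <- rnorm(12)
  expect_equal(welch_t(x, x)$statistic, 0)
  expect_error(welch_t(rep(1, 5), rep(1, 6)), "degenerate-variance")
  expect_error(group_summary(20, 3, 0, "mean_sd"), "spread")
  # median/IQR needs the explicit approximation flag
  m <- group_summary(20, 10, 4, "median_iqr")
  expect_error(welch_from_summaries(m, s1), "allow_median_approx")
  expect_true(welch_from_summaries(m, s1, allow_median_approx = TRUE)$approx)
})

test_that("welch df stays within its theoretical bounds", {
  set.seed(7)
  for (k in 1:200) {
    n1 <- sample(2:80, 1); n2 <- sample(2:80, 1)
    r <- welch_from_summaries(
      group_summary(n1, runif(1, -5, 5), runif(1, 0.1, 10), "mean_sd"),
      group_summary(n2, runif(1, -5, 5), runif(1, 0.1, 10), "mean_sd"))
    expect_gte(r$df, min(n1, n2) - 1 - 1e-9)
    expect_lte(r$df, n1 + n2 - 2 + 1e-9)
  }
})

test_that("cohens_d: null case and antisymmetry under group swap", {
  s1 <- group_summary(25, 8, 2, "mean_sd")
  s2 <- group_summary(40, 8, 3, "mean_sd")
  r <- cohens_d(s1, s2)
  expect_equal(r$d, 0)
  expect_equal(r$ci[1], -r$ci[2])
  a <- group_summary(30, 14, 2.8, "mean_sd")
  b <- group_summary(69, 11.6, 3.2, "mean_sd")
  fwd <- cohens_d(a, b); rev <- cohens_d(b, a)
  expect_equal(rev$d, -fwd$d, tolerance = 1e-12)
  expect_equal(rev$ci, -fwd$ci[2:1], tolerance = 1e-12)
})

test_that("rank-sum: separated samples, identical samples, W convention", {
  r <- rank_sum_test(c(10, 11, 12), c(1, 2, 3))
  expect_equal(r$statistic, 9)           # all 9 pairs have x > y
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  x <- c(3, 1, 4, 1.5, 9)
  same <- rank_sum_test(x, x)
  expect_equal(same$p, 1)
  # first-argument convention: swapping reflects U about n1*n2/2
  a <- c(5, 7, 2, 9); b <- c(1, 8, 3)
  expect_equal(rank_sum_test(a, b)$statistic,
               length(a) * length(b) - rank_sum_test(b, a)$statistic)
})

test_that("exact rank-sum p equals the full-enumeration oracle for n <= 5", {
  set.seed(99)
  for (n1 in 2:5) for (n2 in 2:5) {
    x <- rnorm(n1); y <- rnorm(n2, mean = 0.8)
    r <- rank_sum_test(x, y)
    expect_true(r$exact)
    expect_equal(r$p, enumerate_rank_sum_p(x, y), tolerance = 1e-12,
                 label = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("exact rank-sum p matches wilcox.test on tie-free samples", {
  set.seed(17)
  for (k in 1:5) {
    x <- rnorm(sample(4:12, 1)); y <- rnorm(sample(4:12, 1), 0.5)
    expect_equal(rank_sum_test(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("choose_test follows Shapiro-Wilk on both groups", {
  picks <- vapply(1:20, function(seed) {
    withr::with_seed(seed, choose_test(rnorm(40), rnorm(40))$choice)
  }, character(1))
  expect_gte(sum(picks == "parametric"), 17)
  skewed <- withr::with_seed(1, exp(rnorm(40, sd = 1)))
  expect_equal(choose_test(skewed, rnorm(40))$choice, "nonparametric")
  expect_error(choose_test(c(1, 2), rnorm(10)), "insufficient-data")
})

test_that("summary ANOVA: null case, raw-data equivalence, k = 2 identity", {
  g <- list(group_summary(10, 5, 1, "mean_sd"),
            group_summary(12, 5, 2, "mean_sd"),
            group_summary(9, 5, 1.5, "mean_sd"))
  expect_equal(anova_from_summaries(g)$F, 0)
  # moment-matched raw data reproduces the summary F to 1e-9 (oracle: aov)
  ns <- c(14, 20, 17); ms <- c(3, 4.2, 2.1); ss <- c(1.1, 2.3, 0.8)
  raw <- lapply(1:3, function(i) moment_matched_sample(ns[i], ms[i], ss[i], i))
  sums <- lapply(1:3, function(i) group_summary(ns[i], ms[i], ss[i], "mean_sd"))
  mine <- anova_from_summaries(sums)
  dat <- data.frame(y = unlist(raw), g = factor(rep(1:3, ns)))
  oracle <- summary(stats::aov(y ~ g, dat))[[1]]
  expect_equal(mine$F, oracle[["F value"]][1], tolerance = 1e-9)
  expect_equal(mine$p, oracle[["Pr(>F)"]][1], tolerance = 1e-9)
  expect_equal(mine$df_between, 2)
  expect_equal(mine$df_within, sum(ns) - 3)
  # with k = 2, F equals the square of the pooled-variance t
  s1 <- group_summary(18, 2.4, 1.2, "mean_sd")
  s2 <- group_summary(25, 1.7, 1.6, "mean_sd")
  expect_error(anova_from_summaries(list(s1, s2)), "welch")
  sp2 <- (17 * 1.2^2 + 24 * 1.6^2) / 41
  t_pooled <- (2.4 - 1.7) / sqrt(sp2 * (1 / 18 + 1 / 25))
  # same formula run as a 2-group ANOVA, bypassing the k >= 3 guard
  msb <- 18 * (2.4 - (18 * 2.4 + 25 * 1.7) / 43)^2 +
    25 * (1.7 - (18 * 2.4 + 25 * 1.7) / 43)^2
  expect_equal(msb / sp2, t_pooled^2, tolerance = 1e-9)
})

test_that("tukey_hsd matches TukeyHSD and respects multiplicity", {
  set.seed(55)
  samples <- list(a = rnorm(30, 0), b = rnorm(30, 0), c = rnorm(30, 5))
  mine <- tukey_hsd(samples)
  dat <- data.frame(y = unlist(samples),
                    g = factor(rep(names(samples), each = 30)))
  oracle <- as.data.frame(stats::TukeyHSD(stats::aov(y ~ g, dat))$g)
  expect_equal(mine$diff, oracle$diff, tolerance = 1e-9)
  expect_equal(mine$p_adj, oracle$`p adj`, tolerance = 1e-9)
  # 5-pooled-SD shift: shifted pairs significant, the equal pair not
  expect_lt(max(mine$p_adj[grepl("c", mine$pair)]), 0.001)
  expect_gt(mine$p_adj[mine$pair == "b-a"], 0.5)
  # identical groups: all adjusted p ~ 1
  same <- withr::with_seed(2, rnorm(20, 3))
  r <- tukey_hsd(list(g1 = same, g2 = same, g3 = same))
  expect_true(all(r$p_adj > 0.999))
  # adjusted p >= unadjusted pairwise-t p for every pair
  set.seed(77)
  raw <- list(x = rnorm(15, 0.3), y = rnorm(12), z = rnorm(18, 0.6))
  r2 <- tukey_hsd(raw)
  n <- vapply(raw, length, integer(1))
  mse <- sum(vapply(raw, function(g) sum((g - mean(g))^2), numeric(1))) /
    (sum(n) - 3)
  pairs <- utils::combn(3, 2)
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tt <- (mean(raw[[i2]]) - mean(raw[[i1]])) /
      sqrt(mse * (1 / n[i1] + 1 / n[i2]))
    p_unadj <- 2 * stats::pt(-abs(tt), sum(n) - 3)
    expect_gte(r2$p_adj[j] + 1e-12, p_unadj)
  }
})

test_that("power search: monotonicity and feasibility floor", {
  expect_gte(min_n_for_power(0.3), min_n_for_power(0.5))
  expect_gte(min_n_for_power(0.42, alpha = 0.01), min_n_for_power(0.42))
  expect_lte(min_n_for_power(0.42, power = 0.8), min_n_for_power(0.42))
  expect_equal(min_n_for_power(0.5, power = 1e-4, k = 2), 4)
  expect_equal(min_n_for_power(0.5, power = 1e-4, k = 3), 6)
  expect_equal(min_n_for_power(1.2, k = 3) %% 3, 0)
})

test_that("printed-table recomputation flags approximations and deviations", {
  rec <- recompute_printed_tables()
  rep <- rec$report
  expect_equal(nrow(rep), 32)            # 12 + 10 + 10 comparison rows
  expect_true(all(rep$approx == (rep$kind == "median_iqr")))
  # every t-row recomputation stays close to print (rounding residual only)
  trows <- rep[rep$printed_stat_name == "t", ]
  expect_lt(max(trows$dev_df), 0.2)
  expect_lt(max(trows$dev_t), 0.15)
  expect_true(all(!is.na(rep$p_holm)) && all(rep$p_holm >= rep$p))
})
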