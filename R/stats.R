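#' Group summary (n, location, spread)
#'
#' Summary-statistics container used by the summary-based tests: either
#' mean/SD (`kind = "mean_sd"`) or median/IQR (`kind = "median_iqr"`, as
#' printed for non-normal variables).
#'
#' @param n group size (>= 2).
#' @param location mean or median.
#' @param spread SD or IQR (> 0), same units as `location`.
#' @param kind `"mean_sd"` or `"median_iqr"`.
#' @param label group label.
#' @return object of class `group_summary`.
#' @export
group_summary <- function(n, location, spread, kind = c("mean_sd", "median_iqr"),
                          label = "") {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 2L) stop("group_summary: n must be >= 2")
  if (!is.finite(spread) || spread <= 0) stop("group_summary: spread must be > 0")
  structure(list(n = n, location = location, spread = spread,
                 kind = kind, label = label),
            class = "group_summary")
}

#' Summarize a raw sample
#' @param x numeric sample.
#' @inheritParams group_summary
#' @return a [group_summary()] (mean/SD of `x`).
#' @export
summarize_sample <- function(x, label = "") {
  x <- as.numeric(x)
  group_summary(length(x), mean(x), stats::sd(x), "mean_sd", label)
}

# convert a median/IQR summary to an approximate mean/SD one (normality
# assumption: mean ~ median, SD ~ IQR / 1.349)
approx_mean_sd <- function(s) {
  if (s$kind == "mean_sd") return(s)
  group_summary(s$n, s$location, s$spread / (2 * stats::qnorm(0.75)),
                "mean_sd", s$label)
}

#' Cohen's d with 95% confidence interval, from summaries
#'
#' Pooled-SD standardized mean difference
#' `d = (m1 - m2) / s_p`, `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)`,
#' with the normal-approximation (Hedges-Olkin) interval
#' `d +/- 1.96 sqrt((n1+n2)/(n1 n2) + d^2 / (2 (n1+n2)))`.
#'
#' @param s1,s2 [group_summary()] objects (`mean_sd`; median/IQR summaries
#'   are converted under a normality assumption when
#'   `allow_median_approx = TRUE`).
#' @param allow_median_approx accept median/IQR summaries?
#' @param conf confidence level.
#' @return list with `d`, `ci` (length-2), and `approx` flag.
#' @export
cohens_d <- function(s1, s2, allow_median_approx = FALSE, conf = 0.95) {
  approx <- s1$kind == "median_iqr" || s2$kind == "median_iqr"
  if (approx && !allow_median_approx)
    stop("median/IQR summaries need allow_median_approx = TRUE")
  s1 <- approx_mean_sd(s1); s2 <- approx_mean_sd(s2)
  n1 <- s1$n; n2 <- s2$n
  sp2 <- ((n1 - 1) * s1$spread^2 + (n2 - 1) * s2$spread^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("degenerate-variance error: zero pooled variance")
  d <- (s1$location - s2$location) / sqrt(sp2)
  list(d = d, ci = cohens_d_ci(d, n1, n2, conf), approx = approx)
}

#' @rdname cohens_d
#' @param d a standardized mean difference (e.g. a published value).
#' @param n1,n2 group sizes.
#' @export
cohens_d_ci <- function(d, n1, n2, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  c(d - z * se, d + z * se)
}

new_comparison_result <- function(statistic_name, statistic, df, p, d, d_ci,
                                  direction, approx = FALSE, extra = list()) {
  structure(c(list(statistic_name = statistic_name, statistic = statistic,
                   df = df, p = p, d = d, d_ci = d_ci,
                   direction = direction, approx = approx), extra),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  if (identical(x$statistic_name, "t")) {
    cat(sprintf("Welch t(%.1f) = %.3f, p = %.4g, d = %.2f [%.2f, %.2f]\n",
                x$df, x$statistic, x$p, x$d, x$d_ci[1], x$d_ci[2]))
  } else {
    cat(sprintf("Rank-sum U = %.1f, p = %.4g, d = %.2f [%.2f, %.2f]\n",
                x$statistic, x$p, x$d, x$d_ci[1], x$d_ci[2]))
  }
  cat("direction: ", x$direction, "\n", sep = "")
  invisible(x)
}

#' Welch's t test from group summaries
#'
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p from the t distribution. The sign
#' convention is first group minus second group. Effect size (pooled-SD
#' Cohen's d with 95% CI) is attached.
#'
#' @inheritParams cohens_d
#' @return a `comparison_result` (statistic, df, p, d, d_ci).
#' @export
welch_from_summaries <- function(s1, s2, allow_median_approx = FALSE) {
  approx <- s1$kind == "median_iqr" || s2$kind == "median_iqr"
  if (approx && !allow_median_approx)
    stop("median/IQR summaries need allow_median_approx = TRUE")
  a <- approx_mean_sd(s1); b <- approx_mean_sd(s2)
  v1 <- a$spread^2 / a$n; v2 <- b$spread^2 / b$n
  if (v1 + v2 <= 0) stop("degenerate-variance error: zero variance")
  tstat <- (a$location - b$location) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (a$n - 1) + v2^2 / (b$n - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  es <- cohens_d(s1, s2, allow_median_approx = allow_median_approx)
  new_comparison_result("t", tstat, df, p, es$d, es$ci,
                        direction = "positive statistic: first group larger",
                        approx = approx)
}

#' Welch's t test from raw samples
#'
#' Definitionally identical to [welch_from_summaries()] applied to the
#' samples' own mean/SD/n.
#'
#' @param x,y numeric samples (n >= 2 each).
#' @return a `comparison_result`.
#' @export
welch_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("degenerate-variance error: both samples constant")
  welch_from_summaries(summarize_sample(x, "x"), summarize_sample(y, "y"))
}

#' Mann-Whitney rank-sum test
#'
#' Statistic convention: `U = #{(i,j): x_i > y_j} + 0.5 #ties`, computed
#' with the first argument as the first group. The p-value is exact (from
#' the null permutation distribution) when `n1 * n2 <= 400` and there are
#' no ties, otherwise a normal approximation with tie correction and
#' continuity correction is used. The paper's tables label this statistic
#' W; it tests the same hypothesis as the "Wilcoxon" rows there. Cohen's d
#' from the samples' mean/SD is attached, matching the tables' practice of
#' reporting d alongside W.
#'
#' @param x,y numeric samples.
#' @return a `comparison_result` with `statistic_name = "W"`, `df = NA`.
#' @export
rank_sum_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("empty-input error")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 * n2 <= 400) {
    # exact tail from the null distribution of U
    lo <- stats::pwilcox(U, n1, n2)
    hi <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(lo, hi))
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tt <- table(c(x, y))
    tiecorr <- sum(tt^3 - tt) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * (N + 1 - tiecorr))
    z <- (U - mu - sign(U - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  es <- if (n1 >= 2 && n2 >= 2 && (stats::sd(x) > 0 || stats::sd(y) > 0))
    cohens_d(summarize_sample(x), summarize_sample(y))
  else list(d = NA_real_, ci = c(NA_real_, NA_real_))
  new_comparison_result(
    "W", U, NA_real_, p, es$d, es$ci,
    direction = "U = pairs with first-group value larger (+ half ties)",
    extra = list(exact = !ties && n1 * n2 <= 400))
}

#' Choose parametric vs nonparametric test
#'
#' Shapiro-Wilk normality check per group: the nonparametric route is
#' chosen iff either group rejects normality at `alpha_norm`.
#'
#' @param x,y numeric samples, n >= 3 each.
#' @param alpha_norm significance level for the normality test.
#' @return list with `choice` (`"parametric"`/`"nonparametric"`) and
#'   `shapiro_p` (per-group p-values).
#' @export
choose_test <- function(x, y, alpha_norm = 0.05) {
  if (length(x) < 3L || length(y) < 3L)
    stop("insufficient-data error: normality testing needs n >= 3 per group")
  px <- stats::shapiro.test(x)$p.value
  py <- stats::shapiro.test(y)$p.value
  list(choice = if (min(px, py) < alpha_norm) "nonparametric" else "parametric",
       shapiro_p = c(x = px, y = py))
}

#' One-way ANOVA from group summaries
#'
#' `F = [sum n_i (m_i - m)^2 / (k-1)] / [sum (n_i - 1) s_i^2 / (N - k)]`
#' with p from the F distribution. For two groups use a t test instead
#' (this F equals the square of the pooled-variance t there).
#'
#' @param groups list of [group_summary()] objects (>= 3, `mean_sd`; median/IQR
#'   converted when `allow_median_approx = TRUE`).
#' @inheritParams cohens_d
#' @return object of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`, and `tukey_pairs` (NULL here; see [tukey_hsd()]).
#' @export
anova_from_summaries <- function(groups, allow_median_approx = FALSE) {
  k <- length(groups)
  if (k < 3L)
    stop("fewer than 3 groups: use welch_from_summaries for two groups")
  approx <- any(vapply(groups, function(s) s$kind == "median_iqr", logical(1)))
  if (approx && !allow_median_approx)
    stop("median/IQR summaries need allow_median_approx = TRUE")
  groups <- lapply(groups, approx_mean_sd)
  n <- vapply(groups, function(s) as.numeric(s$n), numeric(1))
  m <- vapply(groups, function(s) s$location, numeric(1))
  s <- vapply(groups, function(s) s$spread, numeric(1))
  N <- sum(n)
  gm <- sum(n * m) / N
  msb <- sum(n * (m - gm)^2) / (k - 1)
  msw <- sum((n - 1) * s^2) / (N - k)
  if (msw <= 0) stop("degenerate-variance error")
  Fv <- msb / msw
  structure(list(F = Fv, df_between = k - 1, df_within = N - k,
                 p = stats::pf(Fv, k - 1, N - k, lower.tail = FALSE),
                 tukey_pairs = NULL, approx = approx),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  if (!is.null(x$tukey_pairs)) {
    cat("Tukey HSD:\n")
    print(x$tukey_pairs)
  }
  invisible(x)
}

#' One-way ANOVA on raw samples, with Tukey HSD
#'
#' @param samples named list of numeric vectors (>= 3 groups, n >= 2 each).
#' @return an `anova_result` including `tukey_pairs`.
#' @export
anova_oneway <- function(samples) {
  if (length(samples) < 3L)
    stop("fewer than 3 groups: use welch_t for two groups")
  res <- anova_from_summaries(lapply(names(samples), function(nm)
    summarize_sample(samples[[nm]], nm)))
  res$tukey_pairs <- tukey_hsd(samples)
  res
}

#' Tukey HSD pairwise comparisons
#'
#' Tukey-Kramer procedure on raw samples: pairwise mean differences with
#' adjusted p-values from the studentized range distribution,
#' `q = |m_i - m_j| / sqrt(MSE/2 (1/n_i + 1/n_j))`, df = N - k.
#'
#' @param samples named list of numeric vectors (>= 3 groups, n >= 2 each).
#' @param conf confidence level for the simultaneous intervals.
#' @return data.frame: `pair`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(samples, conf = 0.95) {
  k <- length(samples)
  if (k < 3L) stop("fewer than 3 groups: use welch_t for two groups")
  if (is.null(names(samples)) || any(names(samples) == ""))
    names(samples) <- paste0("group", seq_len(k))
  n <- vapply(samples, length, integer(1))
  if (any(n < 2L)) stop("each group needs n >= 2")
  m <- vapply(samples, mean, numeric(1))
  N <- sum(n)
  mse <- sum(vapply(samples, function(g) sum((g - mean(g))^2), numeric(1))) /
    (N - k)
  pr <- utils::combn(k, 2)
  diff <- m[pr[2, ]] - m[pr[1, ]]
  se <- sqrt(mse / 2 * (1 / n[pr[1, ]] + 1 / n[pr[2, ]]))
  q <- abs(diff) / se
  p_adj <- stats::ptukey(q, k, N - k, lower.tail = FALSE)
  qcrit <- stats::qtukey(conf, k, N - k)
  data.frame(
    pair = paste(names(samples)[pr[2, ]], names(samples)[pr[1, ]], sep = "-"),
    diff = unname(diff),
    lwr = unname(diff - qcrit * se),
    upr = unname(diff + qcrit * se),
    p_adj = unname(p_adj),
    stringsAsFactors = FALSE
  )
}

#' Minimum sample size for a target power (noncentral F)
#'
#' Smallest total N, balanced over `k` groups (N a multiple of k), such
#' that a one-way fixed-effects ANOVA with effect size Cohen's f reaches
#' the target power at level alpha. Power is evaluated exactly on the
#' noncentral F distribution with noncentrality `lambda = f^2 N`.
#'
#' @param effect_f Cohen's f (> 0).
#' @param alpha significance level.
#' @param power target power in (0, 1).
#' @param k number of groups (>= 2).
#' @return minimum total N (integer, multiple of `k`).
#' @export
min_n_for_power <- function(effect_f, alpha = 0.05, power = 0.90, k = 2L) {
  stopifnot(effect_f > 0, alpha > 0, alpha < 1, power > 0, power < 1, k >= 2)
  N <- 2L * k
  repeat {
    df2 <- N - k
    pw <- stats::pf(stats::qf(1 - alpha, k - 1, df2), k - 1, df2,
                    ncp = effect_f^2 * N, lower.tail = FALSE)
    if (pw >= power) return(N)
    N <- N + k
    if (N > 1e6) stop("bound error: power unreachable within N <= 1e6")
  }
}
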