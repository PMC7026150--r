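# full-enumeration null distribution of the Mann-Whitney U statistic:
# every assignment of which ranks belong to the first sample
enumerate_rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vals <- c(x, y)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  picks <- utils::combn(n1 + n2, n1)
  u_all <- apply(picks, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  lo <- mean(u_all <= u_obs + 1e-9)
  hi <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# sample with exactly the requested mean and SD (moment matching)
moment_matched_sample <- function(n, m, s, seed = 1) {
  z <- withr::with_seed(seed, stats::rnorm(n))
  m + s * as.numeric(scale(z))
}

# two-class Gaussian feature table over the 11 canonical features
gaussian_classes <- function(n_per_class, mu_m, mu_f, sd = rep(1, 11),
                             seed = 1) {
  withr::with_seed(seed, {
    Xm <- sweep(matrix(stats::rnorm(n_per_class * 11), n_per_class) %*%
                  diag(sd), 2, mu_m, "+")
    Xf <- sweep(matrix(stats::rnorm(n_per_class * 11), n_per_class) %*%
                  diag(sd), 2, mu_f, "+")
  })
  X <- rbind(Xm, Xf)
  colnames(X) <- feature_names()
  df <- data.frame(subject_id = sprintf("s%03d", seq_len(2 * n_per_class)))
  cbind(df, as.data.frame(X))
}

table1_moments <- function() {
  tab <- printed_tables()
  t1 <- tab[tab$table == "table1" & tab$variable != "facial_area", ]
  conv <- function(s, kind) ifelse(kind == "median_iqr", s / (2 * qnorm(0.75)), s)
  list(features = t1$variable,
       mean_m = setNames(t1$loc1, t1$variable),
       sd_m = setNames(conv(t1$spread1, t1$kind), t1$variable),
       mean_f = setNames(t1$loc2, t1$variable),
       sd_f = setNames(conv(t1$spread2, t1$kind), t1$variable))
}
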