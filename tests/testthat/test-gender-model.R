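fn <- feature_names()

test_that("the discriminant axis concentrates on the informative feature", {
  # well-separated isotropic classes differing on axis 1 only: the closed
  # form is w = Sigma^-1 (mu_m - mu_f) = (6, 0, ..., 0)
  mu_m <- setNames(rep(0, 11), fn); mu_m[1] <- 6
  mu_f <- setNames(rep(0, 11), fn)
  df <- gaussian_classes(500, mu_m, mu_f, seed = 3)
  labels <- rep(c("male", "female"), each = 500)
  model <- fit_lda(df, labels)
  w <- model$weights
  expect_gt(abs(w[1]) / sqrt(sum(w^2)), 0.99)
})

test_that("score calibration anchors: female mean 5, male mean 15, midpoint 10", {
  mu_m <- setNames(rep(10, 11), fn) + seq(0.5, 5.5, 0.5)
  mu_f <- setNames(rep(10, 11), fn)
  df <- gaussian_classes(100, mu_m, mu_f, seed = 8)
  labels <- rep(c("male", "female"), each = 100)
  model <- fit_lda(df, labels)
  as_row <- function(v) as.data.frame(as.list(setNames(v, fn)))
  mid <- (model$male_mean + model$female_mean) / 2
  expect_equal(unname(masculinity_score(model, as_row(model$female_mean))), 5)
  expect_equal(unname(masculinity_score(model, as_row(model$male_mean))), 15)
  expect_equal(unname(masculinity_score(model, as_row(mid))), 10)
  # two half-distances beyond the male mean clips at 20
  far <- model$male_mean + 1.2 * (model$male_mean - mid)
  expect_equal(unname(masculinity_score(model, as_row(far))), 20)
  deep <- model$female_mean - 3 * (mid - model$female_mean)
  expect_equal(unname(masculinity_score(model, as_row(deep))), 0)
  # classification of the anchors, and the documented midpoint tie rule
  expect_equal(classify(model, as_row(model$male_mean)), "male")
  expect_equal(classify(model, as_row(model$female_mean)), "female")
  expect_equal(classify(model, as_row(mid)), "male")
})

test_that("scores are invariant under affine rescaling of the feature space", {
  tm <- table1_moments()
  df <- gaussian_classes(60, tm$mean_m, tm$mean_f,
                         sd = (tm$sd_m + tm$sd_f) / 2, seed = 4)
  labels <- rep(c("male", "female"), each = 60)
  model <- fit_lda(df, labels, regularization = 0)
  s0 <- masculinity_score(model, df)
  A <- withr::with_seed(9, matrix(stats::rnorm(121, sd = 0.3), 11) + diag(11))
  b <- seq_len(11) * 10
  X <- as.matrix(df[, fn])
  df2 <- df; df2[, fn] <- sweep(X %*% A, 2, b, "+")
  s1 <- masculinity_score(fit_lda(df2, labels, regularization = 0), df2)
  expect_equal(unname(s1), unname(s0), tolerance = 1e-6)
})

test_that("swapping the class distributions reflects the score about 10", {
  tm <- table1_moments()
  df <- gaussian_classes(80, tm$mean_m, tm$mean_f,
                         sd = (tm$sd_m + tm$sd_f) / 2, seed = 12)
  labels <- rep(c("male", "female"), each = 80)
  swapped <- rep(c("female", "male"), each = 80)
  m1 <- fit_lda(df, labels)
  m2 <- fit_lda(df, swapped)
  # probe near the class means so neither score clips
  probe <- df[c(1, 81), ]
  expect_equal(unname(masculinity_score(m2, probe)),
               20 - unname(masculinity_score(m1, probe)), tolerance = 1e-6)
})

test_that("no class signal means no separation of projected means", {
  mu <- setNames(rep(50, 11), fn)
  seps <- vapply(1:10, function(seed) {
    df <- gaussian_classes(50, mu, mu, seed = seed)
    labels <- rep(c("male", "female"), each = 50)
    m <- fit_lda(df, labels)
    half <- (m$projected_male_mean - m$projected_female_mean) / 2
    sdp <- stats::sd(facemasc:::project_features(m, df))
    half / sdp
  }, numeric(1))
  # LDA always oversplits in-sample; just require no systematic separation
  expect_lt(stats::median(seps), 0.75)
})

test_that("parameter recovery: axis direction at n = 200 per class", {
  delta <- withr::with_seed(21, stats::rnorm(11))
  mu_f <- setNames(rep(30, 11), fn)
  mu_m <- mu_f + delta
  df <- gaussian_classes(200, mu_m, mu_f, seed = 22)
  labels <- rep(c("male", "female"), each = 200)
  w <- fit_lda(df, labels)$weights
  cosine <- sum(w * delta) / sqrt(sum(w^2) * sum(delta^2))
  expect_gt(cosine, 0.95)
})

test_that("accuracy: perfect separation 1/1, inverted labels 0/0", {
  mu_m <- setNames(rep(0, 11), fn); mu_m[2] <- 50
  mu_f <- setNames(rep(0, 11), fn)
  df <- gaussian_classes(30, mu_m, mu_f, seed = 6)
  labels <- rep(c("male", "female"), each = 30)
  model <- fit_lda(df, labels)
  expect_equal(unname(classification_accuracy(model, df, labels)), c(1, 1))
  inverted <- rep(c("female", "male"), each = 30)
  expect_equal(unname(classification_accuracy(model, df, inverted)), c(0, 0))
  expect_error(classification_accuracy(model, df, character(0)), "empty-input")
})

test_that("table-1 cohorts are classified near the Bayes bound", {
  # printed per-feature moments imply a Bayes accuracy of ~0.88; LOO LDA at
  # 40/class lands a few points below it (the >= 0.90 acceptance gate is
  # checked, and documented as unattainable, in test-acceptance.R)
  accs <- vapply(1:5, function(seed) {
    spec_m <- table_cohort_spec("table1", "group1")
    spec_f <- table_cohort_spec("table1", "group2")
    coh <- rbind(generate_cohort(spec_m, seed = seed),
                 generate_cohort(spec_f, seed = seed + 1000))
    mean(loo_accuracy(coh, coh$sex))
  }, numeric(1))
  expect_gt(mean(accs), 0.80)
})

test_that("model fitting errors: class count, singularity, missing feature", {
  df <- gaussian_classes(20, setNames(rep(1, 11), fn), setNames(rep(0, 11), fn))
  expect_error(fit_lda(df, rep("male", 40)), "class-count")
  df_const <- df; df_const[[fn[3]]] <- 7
  labels <- rep(c("male", "female"), each = 20)
  expect_error(fit_lda(df_const, labels, regularization = 0), "singularity")
  expect_s3_class(fit_lda(df_const, labels, regularization = 1e-6),
                  "gender_model")
  model <- fit_lda(df, labels)
  broken <- df[1, ]; broken[[fn[5]]] <- NULL
  expect_error(classify(model, broken), fn[5])
})

test_that("gender model JSON round-trip preserves scores", {
  tm <- table1_moments()
  df <- gaussian_classes(40, tm$mean_m, tm$mean_f, sd = tm$sd_m, seed = 31)
  labels <- rep(c("male", "female"), each = 40)
  model <- fit_lda(df, labels, seed = 31)
  path <- withr::local_tempfile(fileext = ".json")
  write_gender_model(model, path)
  back <- read_gender_model(path)
  expect_equal(unname(masculinity_score(back, df)),
               unname(masculinity_score(model, df)), tolerance = 1e-12)
  expect_equal(back$metadata$n_male, 40)
})
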