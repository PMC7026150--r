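test_that("cohort draws reproduce the requested moments (1/sqrt(n) rate)", {
  spec <- table_cohort_spec("table1", "group1", correlation = 0.3)
  for (n in c(400L, 10000L)) {
    big <- cohort_spec("big", n, spec$means, spec$sds,
                       correlation = spec$correlation)
    coh <- generate_cohort(big, seed = 42)
    X <- as.matrix(coh[, feature_names()])
    expect_true(all(abs(colMeans(X) - spec$means) <=
                      3 * spec$sds / sqrt(n)))
    expect_true(all(abs(apply(X, 2, sd) / spec$sds - 1) < 6 / sqrt(n)))
  }
})

test_that("correlation control: independence at rho = 0, recovery at 0.3", {
  spec <- table_cohort_spec("table1", "group2")
  for (rho in c(0, 0.3)) {
    big <- cohort_spec("c", 10000L, spec$means, spec$sds, correlation = rho)
    coh <- generate_cohort(big, seed = 9)
    R <- cor(as.matrix(coh[, feature_names()]))
    off <- R[upper.tri(R)]
    expect_true(all(abs(off - rho) < 0.05))
  }
  bad <- matrix(-0.5, 11, 11); diag(bad) <- 1
  expect_error(cohort_spec("x", 10, spec$means, spec$sds, correlation = bad),
               "positive-definite")
})

test_that("generators are deterministic under a fixed seed", {
  spec <- table_cohort_spec("table2", "group1")
  expect_identical(generate_cohort(spec, seed = 5),
                   generate_cohort(spec, seed = 5))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study_bundle(generate_study(seed = 3), d1)
  write_study_bundle(generate_study(seed = 3), d2)
  for (f in c("features.csv", "proband_scores.csv", "manifest.json"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  # a different seed changes the draws
  expect_false(identical(generate_cohort(spec, seed = 5),
                         generate_cohort(spec, seed = 6)))
})

test_that("study bundle has the published group structure", {
  bundle <- generate_study(seed = 11)
  sizes <- table(bundle$features$group)
  expect_equal(unname(sizes[c("validation_male", "validation_female",
                              "sibling_male", "control_male",
                              "sibling_female", "control_female")]),
               c(40L, 40L, 30L, 69L, 25L, 60L), ignore_attr = TRUE)
  expect_equal(unname(table(bundle$proband_scores$sex)[c("male", "female")]),
               c(54L, 20L), ignore_attr = TRUE)
  expect_false(any(is.na(bundle$features$facial_area)))
})

test_that("sibling/control cohorts recover the generating effect sizes", {
  # mean recovered d over seeds within 0.1 of the d implied by the
  # generating (table-2) moments, for the 8 dimorphic distances
  spec_s <- table_cohort_spec("table2", "group1")
  spec_c <- table_cohort_spec("table2", "group2")
  tab <- printed_tables()
  dimorphic <- tab$variable[tab$table == "table1" & tab$dimorphic %in% TRUE]
  d_true <- vapply(dimorphic, function(f) {
    sp <- sqrt((29 * spec_s$sds[f]^2 + 68 * spec_c$sds[f]^2) / 97)
    (spec_s$means[f] - spec_c$means[f]) / sp
  }, numeric(1))
  d_hat <- matrix(0, 500, length(dimorphic),
                  dimnames = list(NULL, dimorphic))
  for (s in 1:500) {
    sib <- generate_cohort(spec_s, seed = 2000 + s)
    ctl <- generate_cohort(spec_c, seed = 7000 + s)
    d_hat[s, ] <- vapply(dimorphic, function(f)
      cohens_d(summarize_sample(sib[[f]]), summarize_sample(ctl[[f]]))$d,
      numeric(1))
  }
  expect_true(all(abs(colMeans(d_hat) - d_true) <= 0.1))
})

test_that("generated faces satisfy the geometry invariants", {
  face <- generate_face(face_params(resolution = 4, jitter_sd = 1, seed = 2))
  expect_silent(validate_mesh(face$mesh))
  fe <- extract_features(face$mesh, face$landmarks, refine = 1)
  expect_true(all(unlist(fe[feature_names()]) > 0))
  expect_gt(fe$facial_area, 0)
  # geodesic >= linear on the same landmark pair
  expect_gte(fe$geodesic_nose_height + 1e-9, fe$linear_nose_height)
  expect_gte(fe$geodesic_upper_lip_height + 1e-9, fe$linear_upper_lip_height)
})

test_that("faces scale as exact similarities", {
  p1 <- face_params(size = 1, resolution = 4, jitter_sd = 1, seed = 13)
  p2 <- face_params(size = 1.1, resolution = 4, jitter_sd = 1, seed = 13)
  f1 <- generate_face(p1); f2 <- generate_face(p2)
  fe1 <- extract_features(f1$mesh, f1$landmarks, refine = 1)
  fe2 <- extract_features(f2$mesh, f2$landmarks, refine = 1)
  for (v in feature_names())
    expect_equal(fe2[[v]] / fe1[[v]], 1.1, tolerance = 1e-6)
  expect_equal(fe2$facial_area / fe1$facial_area, 1.1^2, tolerance = 1e-6)
})

test_that("dimorphism presets stay inside the published 3-SD envelopes", {
  tm <- table1_moments()
  for (preset in c("male", "female")) for (seed in c(7, 8)) {
    face <- generate_face(face_params(preset = preset, jitter_sd = 1,
                                      resolution = 5, seed = seed))
    fe <- extract_features(face$mesh, face$landmarks, refine = 2)
    mu <- if (preset == "male") tm$mean_m else tm$mean_f
    sd <- if (preset == "male") tm$sd_m else tm$sd_f
    got <- unlist(fe[tm$features])
    expect_true(all(abs(got - mu) <= 3 * sd),
                label = sprintf("%s preset, seed %d", preset, seed))
    expect_gt(fe$facial_area, 20000)
    expect_lt(fe$facial_area, 35000)
  }
})

test_that("face parameter validation", {
  expect_error(face_params(size = 0), "size")
  expect_error(face_params(jitter_sd = 4), "jitter_sd")
  expect_error(face_params(resolution = 2), "resolution")
})
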