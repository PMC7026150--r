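#' Cohort specification for the synthetic feature generator
#'
#' Describes one group of subjects as a multivariate normal over the 11
#' facial distances: per-feature means and SDs plus an inter-feature
#' correlation (a scalar equicorrelation or a full 11 x 11 matrix). The
#' default equicorrelation of 0.3 is a plausible magnitude for craniofacial
#' measurements; the true inter-feature correlations are not recoverable
#' from printed group summaries, so this is configurable.
#'
#' @param label group label (used in `group` column and subject ids).
#' @param n group size (>= 2).
#' @param means,sds named numeric vectors over [feature_names()] (mm).
#' @param correlation scalar in [0, 1) or an 11 x 11 positive-definite
#'   correlation matrix.
#' @param sex `"male"`, `"female"`, or NA.
#' @param area_mean,area_sd optional facial-area moments (mm^2); the area
#'   column is drawn independently of the distances when supplied.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(label, n, means, sds, correlation = 0.3,
                        sex = NA_character_, area_mean = NULL, area_sd = NULL) {
  fn <- feature_names()
  if (!all(fn %in% names(means)) || !all(fn %in% names(sds)))
    stop("means and sds must be named over all 11 features")
  means <- means[fn]; sds <- sds[fn]
  if (any(!is.finite(sds)) || any(sds <= 0)) stop("SDs must be > 0")
  if (n < 2L) stop("cohort n must be >= 2")
  p <- length(fn)
  R <- if (is.matrix(correlation)) correlation else {
    m <- matrix(correlation, p, p); diag(m) <- 1; m
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("spec error: correlation matrix not positive-definite")
  structure(list(label = label, n = as.integer(n), means = means, sds = sds,
                 correlation = R, sex = sex,
                 area_mean = area_mean, area_sd = area_sd),
            class = "cohort_spec")
}

# multivariate normal draws via Cholesky (deterministic given RNG state)
rmvnorm_chol <- function(n, mu, Sigma) {
  L <- chol(Sigma)
  z <- matrix(stats::rnorm(n * length(mu)), n)
  sweep(z %*% L, 2, mu, "+")
}

#' Generate a synthetic feature cohort
#'
#' Draws `spec$n` subjects from the multivariate normal defined by the
#' spec. Reproducible: the same `seed` yields identical tables.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return data.frame in the feature-table schema
#'   (`subject_id, sex, group, <11 distances>, facial_area`).
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(seed, {
    D <- diag(spec$sds)
    X <- rmvnorm_chol(spec$n, spec$means, D %*% spec$correlation %*% D)
    area <- if (!is.null(spec$area_mean))
      stats::rnorm(spec$n, spec$area_mean, spec$area_sd) else NA_real_
  })
  colnames(X) <- feature_names()
  out <- data.frame(
    subject_id = sprintf("%s_%03d", spec$label, seq_len(spec$n)),
    sex = spec$sex, group = spec$label, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(X))
  out$facial_area <- area
  out
}

#' Cohort spec from the embedded printed tables
#'
#' Builds a [cohort_spec()] whose moments are the printed group summaries.
#' Median/IQR rows are converted to mean/SD under a normality assumption
#' (mean ~ median, SD ~ IQR/1.349); the converted variables are recorded in
#' the `approx_features` attribute. Tables 2-3 print only the 8 dimorphic
#' distances, so the remaining 3 are filled from the table-1 moments of the
#' same sex (both study arms, i.e. no sibling shift on them), consistent
#' with their non-significance in the validation cohort.
#'
#' @param table `"table1"`, `"table2"`, or `"table3"`.
#' @param group `"group1"` (boys / siblings) or `"group2"` (girls / controls).
#' @param label group label for the spec (defaults to a descriptive name).
#' @param correlation passed to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
table_cohort_spec <- function(table = c("table1", "table2", "table3"),
                              group = c("group1", "group2"),
                              label = NULL, correlation = 0.3) {
  table <- match.arg(table)
  group <- match.arg(group)
  tab <- printed_tables()
  sex <- if (table == "table3") "female" else
    if (table == "table2") "male" else
      if (group == "group1") "male" else "female"
  if (is.null(label)) {
    role <- if (table == "table1") "validation" else
      if (group == "group1") "sibling" else "control"
    label <- paste(role, sex, sep = "_")
  }
  pick <- function(tb, var) tab[tab$table == tb & tab$variable == var, ]
  loc_col <- if (group == "group1") "loc1" else "loc2"
  spr_col <- if (group == "group1") "spread1" else "spread2"
  n_col <- if (group == "group1") "n1" else "n2"

  fn <- feature_names()
  means <- stats::setNames(numeric(length(fn)), fn)
  sds <- means
  approx_features <- character()
  t1_group <- if (sex == "male") "group1" else "group2"
  t1_loc <- if (t1_group == "group1") "loc1" else "loc2"
  t1_spr <- if (t1_group == "group1") "spread1" else "spread2"
  for (f in fn) {
    row <- pick(table, f)
    src_loc <- loc_col; src_spr <- spr_col
    if (!nrow(row)) {                       # fall back to table-1 same sex
      row <- pick("table1", f)
      src_loc <- t1_loc; src_spr <- t1_spr
    }
    m <- row[[src_loc]]; s <- row[[src_spr]]
    if (row$kind == "median_iqr") {
      s <- s / (2 * stats::qnorm(0.75))
      approx_features <- c(approx_features, f)
    }
    means[f] <- m; sds[f] <- s
  }
  area_row <- pick(table, "facial_area")
  am <- area_row[[loc_col]]; as_ <- area_row[[spr_col]]
  if (area_row$kind == "median_iqr") {
    as_ <- as_ / (2 * stats::qnorm(0.75))
    approx_features <- c(approx_features, "facial_area")
  }
  n <- area_row[[n_col]]
  spec <- cohort_spec(label, n, means, sds, correlation = correlation,
                      sex = sex, area_mean = am, area_sd = as_)
  attr(spec, "approx_features") <- approx_features
  spec
}

#' Unit icosphere mesh
#'
#' Icosahedron subdivided `subdiv` times with vertices projected onto the
#' unit sphere; the workhorse surface for the synthetic face generator and
#' for geodesic accuracy checks (its geodesics have a closed form).
#'
#' @param subdiv number of 1-to-4 triangle subdivisions (>= 0).
#' @param radius sphere radius.
#' @return a [face_mesh()] with `20 * 4^subdiv` faces.
#' @export
icosphere <- function(subdiv = 3L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    ek <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    keys <- edge_key(ek[, 1], ek[, 2])
    ukeys <- unique(keys)
    mid_of <- match(keys, ukeys) + nv
    ue <- ek[!duplicated(keys), , drop = FALSE]
    mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    nf <- nrow(f)
    mab <- mid_of[seq_len(nf)]
    mbc <- mid_of[nf + seq_len(nf)]
    mca <- mid_of[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], mab, mca),
               cbind(f[, 2], mbc, mab),
               cbind(f[, 3], mca, mbc),
               cbind(mab, mbc, mca))
  }
  face_mesh(v * radius, f, subject_id = sprintf("icosphere_%d", subdiv))
}

# ---- synthetic face ---------------------------------------------------------

# head half-axes in mm (x: half-width, y: half-height, z: half-depth) and the
# nasal ridge displacement field, desk-calibrated once so that the default
# face lands near the midpoint of the published male/female distance means
face_shape_constants <- function() {
  list(axes = c(75, 105, 85),
       nose_amp = 13.2, nose_sigma_x = 9,
       nose_peak_y = -9.5, nose_sigma_below = 6, nose_sigma_above = 13)
}

nose_field <- function(x, y, amp, k = face_shape_constants()) {
  sig_y <- ifelse(y < k$nose_peak_y, k$nose_sigma_below, k$nose_sigma_above)
  amp * exp(-(x / k$nose_sigma_x)^2) * exp(-((y - k$nose_peak_y) / sig_y)^2)
}

# z of the face surface at frontal coordinates (x, y), in base (size-1) mm
face_surface_z <- function(x, y, amp, k = face_shape_constants()) {
  r2 <- 1 - (x / k$axes[1])^2 - (y / k$axes[2])^2
  if (any(r2 <= 0)) stop("frontal coordinate outside the head ellipsoid")
  k$axes[3] * sqrt(r2) + nose_field(x, y, amp)
}

# frontal (x, y) landmark targets in base mm; trichion y and nose amplitude
# are the dimorphism controls
landmark_targets <- function(trichion_y = 68, amp = 13.2) {
  xy <- rbind(
    trichion = c(0, trichion_y),
    nasion = c(0, 18),
    pronasale = c(0, -9.5),
    subnasale = c(0, -17.5),
    labiale_superius = c(0, -29),
    stomion = c(0, -40),
    exocanthion_l = c(-42.5, 20),
    exocanthion_r = c(42.5, 20),
    alare_l = c(-7.4, -14),
    alare_r = c(7.4, -14),
    frontotemporale_l = c(-58, 55),
    frontotemporale_r = c(58, 55),
    zygion_r = c(73, -18))
  cbind(xy, z = face_surface_z(xy[, 1], xy[, 2], amp))
}

#' Parameters of the synthetic face generator
#'
#' The generator is a geometric surrogate for a 3D facial scan: a head
#' ellipsoid with a nasal ridge displacement field, carrying the 13
#' canonical landmarks on mesh vertices. It validates geometry code
#' (distances, geodesics, areas); it does not emulate anatomical detail.
#'
#' @param size global similarity scale (1 = child-sized head calibrated to
#'   the published distance scale).
#' @param preset `"neutral"`, `"male"`, or `"female"`: small documented
#'   shifts (global size +/-2.5%, trichion height, nose ridge amplitude)
#'   in the published direction of sexual dimorphism.
#' @param jitter_sd SD (mm) of the random per-landmark displacement before
#'   snapping to the surface; must keep landmarks on-surface (<= 3 mm).
#' @param resolution icosphere subdivision level of the head mesh (>= 3).
#' @param seed integer seed for the jitter field.
#' @return object of class `face_params`.
#' @export
face_params <- function(size = 1, preset = c("neutral", "male", "female"),
                        jitter_sd = 1, resolution = 5L, seed = 1L) {
  preset <- match.arg(preset)
  if (size <= 0) stop("params error: size must be > 0")
  if (jitter_sd < 0 || jitter_sd > 3)
    stop("params error: jitter_sd must be in [0, 3] to keep landmarks on-surface")
  if (resolution < 3L)
    stop("params error: resolution >= 3 needed for a usable triangulation")
  structure(list(size = size, preset = preset, jitter_sd = jitter_sd,
                 resolution = as.integer(resolution), seed = as.integer(seed)),
            class = "face_params")
}

#' Generate a synthetic face mesh with landmarks
#'
#' Builds the head surface at the requested resolution, applies the
#' dimorphism preset, jitters the landmark targets (seeded), and snaps each
#' landmark to the nearest mesh vertex, so every returned landmark lies
#' exactly on the surface. Output is similarity-exact in `size`: the same
#' seed at a different size yields coordinates scaled by that factor.
#'
#' @param params a [face_params()].
#' @param subject_id subject identifier.
#' @return list with `mesh` (a [face_mesh()]) and `landmarks`
#'   (a [landmark_set()]).
#' @export
generate_face <- function(params = face_params(), subject_id = "synthetic") {
  stopifnot(inherits(params, "face_params"))
  k <- face_shape_constants()
  adj <- switch(params$preset,
                neutral = list(scale = 1, trichion_y = 68, amp = k$nose_amp),
                male = list(scale = 1.025, trichion_y = 65, amp = k$nose_amp + 0.7),
                female = list(scale = 0.975, trichion_y = 71, amp = k$nose_amp - 0.7))
  sphere <- icosphere(params$resolution)
  u <- sphere$vertices
  v <- sweep(u, 2, k$axes, "*")
  front <- v[, 3] > 0
  v[front, 3] <- v[front, 3] + nose_field(v[front, 1], v[front, 2], adj$amp)

  targets <- landmark_targets(adj$trichion_y, adj$amp)
  jitter <- withr::with_seed(params$seed,
    matrix(stats::rnorm(length(targets), 0, params$jitter_sd),
           nrow(targets), 3))
  wanted <- targets + jitter
  base_mesh <- face_mesh(v, sphere$faces, subject_id, validate = FALSE)
  # snap each landmark to its nearest free vertex (greedy, fixed landmark
  # order) so coarse meshes cannot collapse two landmarks onto one vertex
  med_edge <- stats::median(sqrt(rowSums(
    (v[sphere$faces[, 1], ] - v[sphere$faces[, 2], ])^2)))
  idx <- integer(nrow(wanted))
  for (i in seq_len(nrow(wanted))) {
    d2 <- (v[, 1] - wanted[i, 1])^2 + (v[, 2] - wanted[i, 2])^2 +
      (v[, 3] - wanted[i, 3])^2
    d2[idx[seq_len(i - 1)]] <- Inf
    idx[i] <- which.min(d2)
    # off-surface guard: beyond what vertex snapping can absorb at this
    # mesh resolution the displacement has left the surface
    if (sqrt(d2[idx[i]]) > max(5, 2 * med_edge))
      stop("params error: landmark displacement pushes a landmark off-surface")
  }
  if (anyDuplicated(idx))
    stop("params error: two landmarks snapped to the same vertex; ",
         "increase resolution or reduce jitter_sd")
  scale <- params$size * adj$scale
  mesh <- face_mesh(v * scale, sphere$faces, subject_id)
  lms <- landmark_set(structure(mesh$vertices[idx, , drop = FALSE],
                                dimnames = list(rownames(targets), NULL)),
                      subject_id = subject_id)
  list(mesh = mesh, landmarks = lms)
}

#' Generate a full synthetic study bundle
#'
#' Emits a complete synthetic replication of the study design: a 40 + 40
#' boy/girl validation cohort drawn from the table-1 moments, male
#' sibling/control cohorts (30 / 69) from the table-2 moments, female
#' sibling/control cohorts (25 / 60) from the table-3 moments, and
#' proband masculinity-score cohorts (54 boys, 20 girls) from the published
#' score moments. Identical seeds yield identical bundles.
#'
#' @param seed integer seed.
#' @param correlation inter-feature correlation for all cohorts.
#' @return list with `features` (long feature table with `sex`/`group`),
#'   `proband_scores` (per-subject scores), and `manifest`.
#' @export
generate_study <- function(seed = 1L, correlation = 0.3) {
  specs <- list(
    table_cohort_spec("table1", "group1", correlation = correlation),
    table_cohort_spec("table1", "group2", correlation = correlation),
    table_cohort_spec("table2", "group1", correlation = correlation),
    table_cohort_spec("table2", "group2", correlation = correlation),
    table_cohort_spec("table3", "group1", correlation = correlation),
    table_cohort_spec("table3", "group2", correlation = correlation))
  features <- do.call(rbind, lapply(seq_along(specs), function(i)
    generate_cohort(specs[[i]], seed = seed + i)))
  pr <- proband_score_summaries()
  proband <- withr::with_seed(seed + 100L, do.call(rbind, lapply(
    seq_len(nrow(pr)), function(i) {
      data.frame(
        subject_id = sprintf("proband_%s_%03d", pr$sex[i], seq_len(pr$n[i])),
        sex = pr$sex[i], group = paste0("proband_", pr$sex[i]),
        score = stats::rnorm(pr$n[i], pr$mean[i], pr$sd[i]),
        stringsAsFactors = FALSE)
    })))
  list(features = features,
       proband_scores = proband,
       manifest = list(seed = seed, correlation = correlation,
                       groups = table(features$group),
                       generator = "facemasc::generate_study",
                       schema_version = 1L))
}

#' Write a study bundle to disk
#'
#' Writes `features.csv`, `proband_scores.csv`, and `manifest.json` into
#' `dir`.
#'
#' @param bundle result of [generate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_features(bundle$features, file.path(dir, "features.csv"))
  utils::write.csv(bundle$proband_scores,
                   file.path(dir, "proband_scores.csv"), row.names = FALSE)
  manifest <- bundle$manifest
  manifest$groups <- as.list(manifest$groups)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
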