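#' Fit the two-class linear discriminant gender model
#'
#' Classical Fisher LDA with equal priors on the 11 facial distances: the
#' discriminant axis is `w = S^-1 (mu_male - mu_female)` where `S` is the
#' pooled within-class covariance, ridge-regularized as
#' `S + regularization * mean(diag(S)) * I`. The axis is male-positive by
#' construction. The fitted object also carries the projected class means,
#' which anchor the 0-20 masculinity score (see [masculinity_score()]).
#'
#' @param features data.frame or matrix holding the 11 canonical distance
#'   columns (see [feature_names()]).
#' @param labels sex label per row; must contain exactly the two classes
#'   `"male"` and `"female"` (each with at least 2 subjects).
#' @param regularization ridge factor, >= 0, in units of the mean within-class
#'   variance. The default 1e-6 keeps the solve well-posed without
#'   materially biasing the axis.
#' @param seed optional integer recorded in the training metadata.
#' @return object of class `gender_model`.
#' @export
fit_lda <- function(features, labels, regularization = 1e-6, seed = NULL) {
  X <- feature_matrix(as.data.frame(features))
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stop("labels must match feature rows")
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("class-count error: need exactly 2 classes, got ", length(classes))
  if (!setequal(classes, c("female", "male")))
    stop("labels must be 'male' and 'female'")
  n_m <- sum(labels == "male"); n_f <- sum(labels == "female")
  if (min(n_m, n_f) < 2L) stop("need >= 2 subjects per class")
  p <- ncol(X)
  if (regularization < 0) stop("regularization must be >= 0")
  if (n_m + n_f <= p && regularization == 0)
    stop("singularity error: n <= 11 requires regularization > 0")

  mu_m <- colMeans(X[labels == "male", , drop = FALSE])
  mu_f <- colMeans(X[labels == "female", , drop = FALSE])
  S <- ((n_m - 1) * stats::cov(X[labels == "male", , drop = FALSE]) +
        (n_f - 1) * stats::cov(X[labels == "female", , drop = FALSE])) /
       (n_m + n_f - 2)
  Sreg <- S + diag(regularization * mean(diag(S)), p)
  w <- tryCatch(solve(Sreg, mu_m - mu_f), error = function(e)
    stop("singularity error: pooled covariance is singular; ",
         "increase regularization"))
  if (!all(is.finite(w))) stop("non-finite discriminant axis")
  names(w) <- colnames(X)

  model <- structure(list(
    weights = w,
    female_mean = mu_f, male_mean = mu_m,
    projected_female_mean = drop(mu_f %*% w),
    projected_male_mean = drop(mu_m %*% w),
    pooled_within_covariance = Sreg,
    regularization = regularization,
    features = colnames(X),
    metadata = list(n_male = n_m, n_female = n_f, seed = seed,
                    schema_version = 1L)
  ), class = "gender_model")
  stopifnot(model$projected_male_mean > model$projected_female_mean)
  model
}

#' @export
print.gender_model <- function(x, ...) {
  cat(sprintf("<gender_model> trained on %d male / %d female faces\n",
              x$metadata$n_male, x$metadata$n_female))
  cat(sprintf("  projected class means: female %.3f, male %.3f\n",
              x$projected_female_mean, x$projected_male_mean))
  invisible(x)
}

project_features <- function(model, features) {
  X <- feature_matrix(as.data.frame(features))
  drop(X[, model$features, drop = FALSE] %*% model$weights)
}

#' Classify sex from the 11 facial distances
#'
#' A face is classified male iff its projection onto the discriminant axis
#' exceeds the midpoint of the projected class means. A projection exactly
#' at the midpoint is classified male (documented tie rule; the tie has
#' probability zero for continuous data).
#'
#' @param model a [fit_lda()] model.
#' @param features data.frame/matrix with the 11 canonical distance columns.
#' @return character vector of `"male"`/`"female"`.
#' @export
classify <- function(model, features) {
  pr <- project_features(model, features)
  mid <- (model$projected_male_mean + model$projected_female_mean) / 2
  ifelse(pr >= mid, "male", "female")
}

#' Facial masculinity score (0-20)
#'
#' Position of a face in discriminant space mapped to a 0-20 scale in which
#' 0 represents extreme femininity and 20 extreme masculinity. Let `u` be
#' the projection's deviation from the midpoint of the projected class
#' means, in units of half the inter-mean distance; the score is
#' `clip(10 + 5 u, 0, 20)`. The female class mean anchors at 5, the male
#' class mean at 15, the midpoint at 10; faces beyond two half-distances
#' past a class mean saturate at 0 or 20.
#'
#' @inheritParams classify
#' @return numeric vector of scores in `[0, 20]`, named by `subject_id`
#'   when available.
#' @export
masculinity_score <- function(model, features) {
  half <- (model$projected_male_mean - model$projected_female_mean) / 2
  if (half <= 0 || !is.finite(half))
    stop("calibration error: projected class means coincide")
  pr <- project_features(model, features)
  mid <- (model$projected_male_mean + model$projected_female_mean) / 2
  u <- (pr - mid) / half
  score <- pmin(pmax(10 + 5 * u, 0), 20)
  df <- as.data.frame(features)
  if ("subject_id" %in% names(df)) names(score) <- df$subject_id
  score
}

#' Per-class classification accuracy
#'
#' @inheritParams classify
#' @param labels true sex per row.
#' @return named numeric vector: fraction correct per class present.
#' @export
classification_accuracy <- function(model, features, labels) {
  labels <- as.character(labels)
  if (!length(labels)) stop("empty-input error: no labelled subjects")
  pred <- classify(model, features)
  vapply(sort(unique(labels)),
         function(cl) mean(pred[labels == cl] == cl),
         numeric(1))
}

#' Leave-one-out classification accuracy
#'
#' Refits the discriminant with each subject held out in turn and reports
#' per-class accuracy of the held-out predictions. This is the honest
#' accuracy estimate when no independent test cohort exists.
#'
#' @inheritParams fit_lda
#' @return named numeric vector, fraction correct per class.
#' @export
loo_accuracy <- function(features, labels, regularization = 1e-6) {
  features <- as.data.frame(features)
  labels <- as.character(labels)
  n <- nrow(features)
  pred <- character(n)
  for (i in seq_len(n)) {
    m <- fit_lda(features[-i, , drop = FALSE], labels[-i],
                 regularization = regularization)
    pred[i] <- classify(m, features[i, , drop = FALSE])
  }
  vapply(sort(unique(labels)),
         function(cl) mean(pred[labels == cl] == cl),
         numeric(1))
}

#' Serialize / restore a gender model (versioned JSON)
#'
#' @param model a `gender_model`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_gender_model` returns the model.
#' @export
write_gender_model <- function(model, path) {
  payload <- list(
    schema = "facemasc/gender_model",
    schema_version = model$metadata$schema_version,
    features = model$features,
    weights = unname(model$weights),
    female_mean = unname(model$female_mean),
    male_mean = unname(model$male_mean),
    projected_female_mean = model$projected_female_mean,
    projected_male_mean = model$projected_male_mean,
    pooled_within_covariance = model$pooled_within_covariance,
    regularization = model$regularization,
    metadata = model$metadata
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gender_model
#' @export
read_gender_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "facemasc/gender_model"))
    stop("not a gender_model file: ", path)
  w <- stats::setNames(as.numeric(p$weights), p$features)
  structure(list(
    weights = w,
    female_mean = stats::setNames(as.numeric(p$female_mean), p$features),
    male_mean = stats::setNames(as.numeric(p$male_mean), p$features),
    projected_female_mean = p$projected_female_mean,
    projected_male_mean = p$projected_male_mean,
    pooled_within_covariance = matrix(unlist(p$pooled_within_covariance),
                                      length(w), length(w)),
    regularization = p$regularization,
    features = p$features,
    metadata = p$metadata
  ), class = "gender_model")
}

#' The package's reference gender model
#'
#' The original training scans are not distributable, so the shipped model
#' is trained deterministically on the synthetic typically-developing
#' validation cohort (40 boys + 40 girls drawn from the published group
#' moments; see [generate_study()]). Retrain on your own feature table with
#' [fit_lda()] for any real analysis.
#'
#' @param seed integer seed for the training cohort.
#' @return a `gender_model`.
#' @export
default_gender_model <- function(seed = 20200116L) {
  bundle <- generate_study(seed = seed)
  val <- bundle$features[bundle$features$group %in%
                           c("validation_male", "validation_female"), ]
  fit_lda(val, val$sex, seed = seed)
}
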