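#' Study configuration
#'
#' Bundles the inputs shared by the three study analyses. `features` and
#' `proband_scores` may be data frames or CSV paths; `model` may be a
#' fitted [fit_lda()] object, a JSON path written by [write_gender_model()],
#' or `NULL` (train on the validation groups of the input, falling back to
#' the packaged synthetic reference model).
#'
#' @param features feature table (data.frame or CSV path) with `sex` and
#'   `group` columns; group labels follow [generate_study()] conventions
#'   (`validation_*`, `sibling_*`, `control_*`).
#' @param proband_scores per-subject proband score table (data.frame or CSV
#'   path) with `sex`, `group`, `score`.
#' @param fixtures run analyses on the embedded printed summary tables
#'   instead of raw features?
#' @param alpha significance level in (0, 1).
#' @param seed integer seed (model training, anything stochastic).
#' @param model see above.
#' @param out_dir optional output directory for [write_report()].
#' @return object of class `study_config`.
#' @export
study_config <- function(features = NULL, proband_scores = NULL,
                         fixtures = FALSE, alpha = 0.05, seed = 1L,
                         model = NULL, out_dir = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("config error: alpha must be in (0,1)")
  if (is.character(features)) features <- read_features(features)
  if (is.character(proband_scores))
    proband_scores <- utils::read.csv(proband_scores, stringsAsFactors = FALSE)
  if (is.character(model)) model <- read_gender_model(model)
  structure(list(features = features, proband_scores = proband_scores,
                 fixtures = fixtures, alpha = alpha, seed = as.integer(seed),
                 model = model, out_dir = out_dir),
            class = "study_config")
}

resolve_model <- function(config) {
  if (!is.null(config$model)) return(config$model)
  feats <- config$features
  if (!is.null(feats)) {
    val <- feats[feats$group %in% c("validation_male", "validation_female"), ]
    if (nrow(val) >= 8 && length(unique(val$sex)) == 2)
      return(fit_lda(val, val$sex, seed = config$seed))
  }
  default_gender_model(seed = config$seed)
}

masc_direction_of <- function(variable) {
  if (variable == "masculinity_score") return(1)
  if (variable == "facial_area") return(NA_real_)
  tab <- printed_tables()
  row <- tab[tab$table == "table1" & tab$variable == variable, ]
  if (!nrow(row)) NA_real_ else row$masc_direction
}

# one comparison row: assumption check, test choice, statistics, direction
compare_row <- function(variable, x, y, alpha, masc_dir = NA_real_) {
  ct <- choose_test(x, y, alpha_norm = 0.05)
  cr <- if (ct$choice == "parametric") welch_t(x, y) else rank_sum_test(x, y)
  diff <- mean(x) - mean(y)
  direction <- if (is.na(masc_dir)) NA_character_
    else if (diff == 0) "no shift"
    else if (sign(diff) == masc_dir) "masculinised" else "feminised"
  data.frame(
    variable = variable, test = ct$choice,
    shapiro_p_group1 = unname(ct$shapiro_p[1]),
    shapiro_p_group2 = unname(ct$shapiro_p[2]),
    statistic_name = cr$statistic_name, statistic = cr$statistic,
    df = cr$df, p = cr$p, d = cr$d, ci_lo = cr$d_ci[1], ci_hi = cr$d_ci[2],
    mean_diff = diff, significant = cr$p < alpha, direction = direction,
    stringsAsFactors = FALSE)
}

#' Validation analysis: classifier accuracy and per-feature dimorphism
#'
#' The table-1 analogue. In data mode, compares boys and girls of the
#' validation cohort on each of the 11 distances plus facial area
#' (Welch's t, or rank-sum when Shapiro-Wilk rejects normality in either
#' group) and reports per-class classification accuracy: leave-one-out when
#' the model was trained on this same cohort, direct otherwise. In fixtures
#' mode, recomputes the printed table-1 statistics from the printed
#' summaries.
#'
#' @param config a [study_config()].
#' @return a report section (list).
#' @export
run_validation <- function(config) {
  alpha <- config$alpha
  if (config$fixtures) {
    rec <- recompute_printed_tables(alpha = alpha)
    rows <- rec$report[rec$report$table == "table1", ]
    return(list(mode = "fixtures", rows = rows,
                significant_features = rec$significant_features_table1,
                accuracy = NULL))
  }
  feats <- config$features
  if (is.null(feats)) stop("config error: no features supplied")
  val <- feats[feats$group %in% c("validation_male", "validation_female"), ]
  if (!nrow(val)) val <- feats
  sexes <- unique(stats::na.omit(val$sex))
  if (length(sexes) != 2)
    stop("config error: validation needs both sexes labelled, got ",
         length(sexes))
  boys <- val[val$sex == "male", ]
  girls <- val[val$sex == "female", ]

  self_trained <- is.null(config$model)
  model <- resolve_model(config)
  acc <- if (self_trained) loo_accuracy(val, val$sex)
         else classification_accuracy(model, val, val$sex)

  vars <- c(feature_names(),
            if (!all(is.na(val$facial_area))) "facial_area")
  rows <- do.call(rbind, lapply(vars, function(v)
    compare_row(v, boys[[v]], girls[[v]], alpha, masc_direction_of(v))))
  list(mode = "data", rows = rows,
       significant_features = sum(rows$significant[rows$variable %in%
                                                     feature_names()]),
       accuracy = as.list(acc),
       accuracy_method = if (self_trained) "leave-one-out" else "holdout")
}

#' Sibling vs control comparison
#'
#' The table-2/3 analogue, run separately per sex: facial area, the 0-20
#' masculinity score (computed through the gender model), and the 8
#' sexually dimorphic distances, each with assumption check, chosen test,
#' statistic, df, p, Cohen's d with CI, and a masculinised/feminised
#' direction annotation. In fixtures mode, recomputes the printed table-2/3
#' statistics instead.
#'
#' @param config a [study_config()].
#' @return list with one section per sex (`male`, `female`).
#' @export
run_sibling_comparison <- function(config) {
  alpha <- config$alpha
  if (config$fixtures) {
    rec <- recompute_printed_tables(alpha = alpha)
    return(list(mode = "fixtures",
                male = list(rows = rec$report[rec$report$table == "table2", ]),
                female = list(rows = rec$report[rec$report$table == "table3", ])))
  }
  feats <- config$features
  if (is.null(feats)) stop("config error: no features supplied")
  model <- resolve_model(config)
  tab <- printed_tables()
  dimorphic <- tab$variable[tab$table == "table1" & tab$dimorphic %in% TRUE]

  arm <- function(sex) {
    sib <- feats[feats$group == paste0("sibling_", sex), ]
    ctl <- feats[feats$group == paste0("control_", sex), ]
    if (nrow(sib) < 2 || nrow(ctl) < 2)
      stop("config error: sibling/control groups need n >= 2 for sex ", sex)
    sib$masculinity_score <- masculinity_score(model, sib)
    ctl$masculinity_score <- masculinity_score(model, ctl)
    vars <- c(if (!all(is.na(sib$facial_area))) "facial_area",
              "masculinity_score", dimorphic)
    rows <- do.call(rbind, lapply(vars, function(v)
      compare_row(v, sib[[v]], ctl[[v]], alpha, masc_direction_of(v))))
    list(rows = rows, n_sibling = nrow(sib), n_control = nrow(ctl))
  }
  list(mode = "data", male = arm("male"), female = arm("female"))
}

#' Normalized kernel density of masculinity scores on the 0-20 grid
#'
#' Gaussian kernel with Silverman's bandwidth, evaluated on a fixed grid of
#' 201 points over [0, 20] and renormalized so the trapezoid integral over
#' the grid is exactly 1 (the kernel mass falling outside the score range
#' is folded back proportionally).
#'
#' @param scores numeric vector of 0-20 scores.
#' @return data.frame with `score` and `density`.
#' @export
score_density <- function(scores, n_grid = 201L) {
  d <- stats::density(scores, bw = stats::bw.nrd0(scores),
                      from = 0, to = 20, n = n_grid)
  dx <- diff(d$x[1:2])
  total <- sum((d$y[-1] + d$y[-n_grid]) / 2) * dx
  data.frame(score = d$x, density = d$y / total)
}

#' Three-group comparison: probands vs siblings vs controls
#'
#' One-way ANOVA with Tukey HSD on masculinity scores, per sex, across the
#' autistic-proband, sibling, and control groups, plus normalized score
#' densities per group (the figure analogue). In fixtures mode the ANOVA is
#' computed from the printed score summaries (probands plus the printed
#' sibling/control score rows; the female sibling/control scores are
#' printed as median/IQR and are converted under the normality
#' approximation), so no Tukey or densities are available there.
#'
#' @param config a [study_config()]; data mode requires `proband_scores`
#'   and sibling/control features for both sexes.
#' @return list with one section per sex.
#' @export
run_three_group <- function(config) {
  if (config$fixtures) {
    tab <- printed_tables()
    pr <- proband_score_summaries()
    arm <- function(sex, table) {
      row <- tab[tab$table == table & tab$variable == "masculinity_score", ]
      pb <- pr[pr$sex == sex, ]
      groups <- list(
        group_summary(pb$n, pb$mean, pb$sd, "mean_sd", "proband"),
        group_summary(row$n1, row$loc1, row$spread1, row$kind, "sibling"),
        group_summary(row$n2, row$loc2, row$spread2, row$kind, "control"))
      anova_from_summaries(groups, allow_median_approx = TRUE)
    }
    return(list(mode = "fixtures",
                male = list(anova = arm("male", "table2")),
                female = list(anova = arm("female", "table3"))))
  }
  feats <- config$features
  proband <- config$proband_scores
  if (is.null(feats) || is.null(proband))
    stop("config error: three-group analysis needs features and proband scores")
  model <- resolve_model(config)
  arm <- function(sex) {
    sib <- feats[feats$group == paste0("sibling_", sex), ]
    ctl <- feats[feats$group == paste0("control_", sex), ]
    pb <- proband[proband$sex == sex, ]
    groups <- list(proband = pb$score,
                   sibling = masculinity_score(model, sib),
                   control = masculinity_score(model, ctl))
    if (any(vapply(groups, length, integer(1)) < 2))
      stop("fewer than 3 usable groups: use run_sibling_comparison ",
           "for two-group contrasts")
    res <- anova_oneway(groups)
    dens <- lapply(groups, score_density)
    list(anova = res, group_means = vapply(groups, mean, numeric(1)),
         densities = dens)
  }
  list(mode = "data", male = arm("male"), female = arm("female"))
}

# small stable checksum so reports can state which config produced them
config_hash <- function(config) {
  s <- jsonlite::toJSON(list(alpha = config$alpha, seed = config$seed,
                             fixtures = config$fixtures,
                             n_features = if (is.null(config$features)) 0L
                                          else nrow(config$features)),
                        auto_unbox = TRUE)
  sum(utf8ToInt(as.character(s)) * seq_along(utf8ToInt(as.character(s)))) %% 2^28
}

#' Run the full study and assemble a report
#'
#' Executes the three analyses ([run_validation()],
#' [run_sibling_comparison()], [run_three_group()]) that the pipeline
#' supports and wraps them with run metadata.
#'
#' @param config a [study_config()].
#' @return object of class `study_report`.
#' @export
run_study <- function(config) {
  three <- tryCatch(run_three_group(config), error = function(e) NULL)
  structure(list(
    metadata = list(package = "facemasc",
                    version = as.character(utils::packageVersion("facemasc")),
                    seed = config$seed, alpha = config$alpha,
                    fixtures = config$fixtures,
                    config_hash = config_hash(config),
                    timestamp = format(Sys.time(), tz = "UTC")),
    validation = run_validation(config),
    sibling_comparison = run_sibling_comparison(config),
    three_group = three
  ), class = "study_report")
}

#' Serialize a study report
#'
#' Writes `report.json` plus one CSV per tabular section into `dir`.
#'
#' @param report a `study_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass_deep(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(report$validation$rows))
    utils::write.csv(report$validation$rows,
                     file.path(dir, "validation.csv"), row.names = FALSE)
  for (sex in c("male", "female")) {
    rows <- report$sibling_comparison[[sex]]$rows
    if (!is.null(rows))
      utils::write.csv(rows, file.path(dir, paste0("sibling_", sex, ".csv")),
                       row.names = FALSE)
  }
  invisible(dir)
}

# strip S3 classes recursively so jsonlite serializes plainly
unclass_deep <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

#' Structural validation of a study report
#'
#' Checks a report against the shipped JSON schema
#' (`inst/extdata/report_schema.json`): required sections, required fields
#' per comparison row, and the density normalization invariant (each
#' density integrates to 1 within 0.01 on its grid).
#'
#' @param report a `study_report` (or a list parsed back from report.json).
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("extdata", "report_schema.json",
                                            package = "facemasc",
                                            mustWork = TRUE))
  for (sec in schema$required_sections)
    if (is.null(report[[sec]])) stop("report missing section: ", sec)
  for (f in schema$required_metadata)
    if (is.null(report$metadata[[f]])) stop("report metadata missing: ", f)
  check_rows <- function(rows, where) {
    if (is.null(rows)) return(invisible())
    rows <- as.data.frame(rows)
    data_ok <- all(unlist(schema$required_row_fields) %in% names(rows))
    fix_ok <- all(unlist(schema$required_row_fields_fixtures) %in% names(rows))
    if (!data_ok && !fix_ok)
      stop(where, " rows match neither the data-mode nor the fixtures-mode ",
           "row schema")
  }
  check_rows(report$validation$rows, "validation")
  for (sex in c("male", "female")) {
    check_rows(report$sibling_comparison[[sex]]$rows,
               paste0("sibling_", sex))
    dens <- report$three_group[[sex]]$densities
    if (!is.null(dens)) {
      for (nm in names(dens)) {
        d <- as.data.frame(dens[[nm]])
        dx <- diff(d$score[1:2])
        tot <- sum((d$density[-1] + d$density[-nrow(d)]) / 2) * dx
        if (abs(tot - 1) > 0.01)
          stop("density for ", sex, "/", nm, " integrates to ", round(tot, 4))
      }
    }
  }
  invisible(TRUE)
}
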