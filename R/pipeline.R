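descriptives_by <- function(cohort, features, grouping) {
  as_tibble(cohort) %>%
    tidyr::pivot_longer(all_of(features), names_to = "feature", values_to = "value") %>%
    group_by(.data$feature, .data[[grouping]]) %>%
    summarise(n = n(), mean = mean(.data$value), sd = sd(.data$value),
              .groups = "drop")
}

#' Run the sex-dimorphism discovery workflow
#'
#' End-to-end analysis of a male/female cohort: per-sex descriptives,
#' mRMR feature ranking, optimal-subset selection by cross-validated
#' linear discriminant accuracy, and per-feature pooled t-tests with
#' r-squared effect sizes for the selected features. Fully reproducible
#' given the cohort and seed.
#'
#' @param cohort Cohort tibble with a `sex` column; if `NULL`, a
#'   synthetic cohort is generated from `spec`.
#' @param spec [cohort_spec()] used when `cohort` is NULL (default
#'   [study1_spec()] at the published moments).
#' @param bins mRMR discretisation bins (default 8).
#' @param variant mRMR criterion variant (`"MID"`/`"MIQ"`).
#' @param folds Cross-validation folds (default 10).
#' @param seed Seed for fold shuffling (and recorded in the report).
#' @param max_subset Largest ranking prefix evaluated.
#' @return A `facedim_study1` report: list with `descriptives`,
#'   `ranking`, `selection`, `cv_accuracy`, `t_tests`, and `meta`.
#' @export
run_study1 <- function(cohort = NULL, spec = study1_spec(seed = seed),
                       bins = 8, variant = "MID", folds = 10,
                       seed = 20150415, max_subset = NULL) {
  if (is.null(cohort)) cohort <- generate_distance_cohort(spec)
  cohort <- validate_cohort(cohort)
  if (!"sex" %in% names(cohort)) abort("Study-1 cohort needs a 'sex' column.")
  if (length(unique(cohort$sex)) != 2) abort("Study-1 cohort needs both sexes.")
  features <- setdiff(cohort_feature_names(cohort), "facial_area")
  if (length(features) < 6) abort("Study-1 cohort needs at least 6 distance features.")

  ranking <- mrmr_rank(cohort, label_column = "sex", features = features,
                       bins = bins, variant = variant)
  selection <- select_optimal_subset(cohort, ranking, label_column = "sex",
                                     folds = folds, seed = seed,
                                     max_size = max_subset)
  t_tests <- cohort_t_tests(cohort, features = selection$features,
                            grouping = "sex", reference = "male")
  structure(list(
    descriptives = descriptives_by(cohort, features, "sex"),
    ranking = ranking,
    selection = selection[c("features", "path")],
    cv_accuracy = selection$accuracy[c("per_class", "overall")],
    t_tests = t_tests,
    meta = report_meta(seed, list(bins = bins, variant = variant, folds = folds))
  ), class = "facedim_study1")
}

#' Run the trait-group comparison workflow for one sex
#'
#' Compares high- vs low-trait groups within one sex on the selected
#' facial distances: pooled t-tests with r-squared, a facial-area control
#' test (group differences in overall face size would confound distance
#' differences), dimorphism-direction calls against a male/female
#' reference, and a discriminant function analysis over the significant
#' features with leave-one-out classification.
#'
#' @param cohort Cohort tibble with `sex` and `group` columns for one
#'   sex; if `NULL`, generated from `spec`.
#' @param spec [cohort_spec()] used when `cohort` is NULL (default:
#'   published moments for `sex`).
#' @param sex Which sex the cohort describes.
#' @param features Distance features to compare (default: the six
#'   dimorphic distances).
#' @param sex_reference Per-feature male-vs-female [summary_t_test()]
#'   rows used to orient dimorphism calls; defaults to the published
#'   sex-comparison moments.
#' @param alpha Significance level (default .05).
#' @param dfa_cv Run leave-one-out CV in the DFA.
#' @param seed Recorded in the report; also seeds generation when
#'   `cohort` is NULL.
#' @return A `facedim_study2` report: list with `descriptives`,
#'   `t_tests`, `area_control`, `direction_calls`, `dfa` and `meta`.
#' @export
run_study2 <- function(cohort = NULL, sex = c("male", "female"),
                       spec = study2_spec(sex, seed = seed),
                       features = NULL, sex_reference = NULL,
                       alpha = 0.05, dfa_cv = TRUE, seed = 20150415) {
  sex <- arg_match(sex)
  if (is.null(cohort)) cohort <- generate_distance_cohort(spec)
  cohort <- validate_cohort(cohort)
  if (!"group" %in% names(cohort)) abort("Study-2 cohort needs a 'group' column.")
  cohort <- dplyr::filter(cohort, is.na(.data$sex) | .data$sex == !!sex)
  if (length(unique(cohort$group)) != 2) abort("Study-2 cohort needs both AQ groups.")
  if (is.null(features)) {
    features <- intersect(study1_table()$feature, cohort_feature_names(cohort))
  }
  if (is.null(sex_reference)) sex_reference <- reference_sex_t_tests()

  t_tests <- cohort_t_tests(cohort, features = features, grouping = "group",
                            reference = "high_AQ")
  area <- NULL
  if ("facial_area" %in% names(cohort)) {
    area <- cohort_t_tests(cohort, features = "facial_area",
                           grouping = "group", reference = "high_AQ")
  }
  calls <- call_dimorphism_direction(sex_reference, t_tests, sex = sex,
                                     alpha = alpha)
  sig <- t_tests$feature[t_tests$p < alpha]
  dfa <- NULL
  if (length(sig) >= 1 && all(table(cohort$group) > length(sig))) {
    dfa <- fit_dfa(cohort, features = sig, group_column = "group",
                   positive_class = "high_AQ", cv = dfa_cv)
  }
  structure(list(
    sex = sex,
    descriptives = descriptives_by(cohort, intersect(c(features, "facial_area"),
                                                     names(cohort)), "group"),
    t_tests = t_tests, area_control = area, direction_calls = calls,
    dfa = dfa,
    meta = report_meta(seed, list(alpha = alpha, features = features))
  ), class = "facedim_study2")
}

#' Per-feature male-vs-female reference tests at the published moments
#'
#' @return Tibble of [summary_t_test()] rows for the six dimorphic
#'   distances, male as group 1.
#' @export
reference_sex_t_tests <- function() {
  tab <- study1_table()
  list_rbind(pmap(tab, function(feature, male_mean, male_sd, female_mean, female_sd) {
    summary_t_test(male_mean, male_sd, 107, female_mean, female_sd, 101,
                   feature = feature)
  }))
}

report_meta <- function(seed, params) {
  list(seed = seed, params = params,
       version = as.character(packageVersion("facedim")),
       config_hash = rlang::hash(list(seed = seed, params = params)))
}

#' @export
print.facedim_study1 <- function(x, ...) {
  cat("== Sex-dimorphism discovery report ==\n")
  cat("Selected features:", paste(x$selection$features, collapse = ", "), "\n")
  acc <- x$cv_accuracy$per_class
  cat(sprintf("Cross-validated accuracy: %s\n",
              paste(sprintf("%s %.2f%%", acc$class, acc$accuracy), collapse = ", ")))
  print(x$t_tests[, c("feature", "t", "df", "p", "r2")])
  invisible(x)
}

#' @export
print.facedim_study2 <- function(x, ...) {
  cat(sprintf("== Trait-group comparison report (%s) ==\n", x$sex))
  print(x$t_tests[, c("feature", "t", "df", "p", "r2")])
  if (!is.null(x$dfa)) print(x$dfa)
  invisible(x)
}

report_to_list <- function(report) {
  drop_class <- function(x) {
    if (inherits(x, "facedim_dfa")) {
      c(x[c("features", "classes", "wilks_lambda", "chi_square", "chi_df", "p",
            "classification_accuracy", "cv_accuracy")],
        list(standardized_coefficients = as.list(x$standardized_coefficients)))
    } else if (is.data.frame(x)) {
      as.data.frame(x)
    } else if (is.list(x)) {
      lapply(x, drop_class)
    } else x
  }
  lapply(unclass(report), drop_class)
}

#' Write a study report to JSON and Markdown
#'
#' Serialises a [run_study1()] or [run_study2()] report to
#' `<stem>.json` (machine-readable, embeds seed, parameter hash and
#' package version) and `<stem>.md` (human-readable tables). Writing is
#' atomic per file: on error no partial file is left behind.
#'
#' @param report A `facedim_study1` or `facedim_study2` object.
#' @param stem Output path without extension.
#' @return Character vector of the two written paths, invisibly.
#' @export
write_report <- function(report, stem) {
  json_path <- paste0(stem, ".json")
  md_path <- paste0(stem, ".md")
  tmp <- tempfile()
  jsonlite::write_json(report_to_list(report), tmp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  file.copy(tmp, json_path, overwrite = TRUE); unlink(tmp)

  lines <- c(
    if (inherits(report, "facedim_study1")) "# Sex-dimorphism discovery report"
    else sprintf("# Trait-group comparison report (%s)", report$sex),
    "",
    sprintf("- seed: %d", report$meta$seed),
    sprintf("- package version: %s", report$meta$version),
    sprintf("- config hash: %s", report$meta$config_hash),
    "",
    "## t-tests",
    md_table(report$t_tests[, c("feature", "t", "df", "p", "r2")])
  )
  if (inherits(report, "facedim_study1")) {
    acc <- report$cv_accuracy$per_class
    lines <- c(lines, "", "## Selection",
               sprintf("- selected: %s", paste(report$selection$features, collapse = ", ")),
               sprintf("- per-class CV accuracy: %s",
                       paste(sprintf("%s %.2f%%", acc$class, acc$accuracy), collapse = ", ")))
  } else if (!is.null(report$dfa)) {
    gl <- glance(report$dfa)
    lines <- c(lines, "", "## Discriminant function analysis",
               md_table(tidy(report$dfa)),
               sprintf("- Wilks' lambda %.3f, chi2(%d) = %.1f, p = %.3g",
                       gl$wilks_lambda, gl$chi_df, gl$chi_square, gl$p),
               sprintf("- classified %.1f%% (leave-one-out %.1f%%)",
                       gl$classification_accuracy, gl$cv_accuracy))
  }
  writeLines(lines, md_path)
  invisible(c(json_path, md_path))
}

md_table <- function(df) {
  fmt <- function(v) if (is.numeric(v)) formatC(v, format = "g", digits = 4) else as.character(v)
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}
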