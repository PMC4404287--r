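#' Names of the 23 classical facial distances
#'
#' @return Character vector of the 23 distance names in their canonical
#'   order (forehead width through lower profile height).
#' @export
distance_names <- function() distance_definitions()$distance

cohort_label_levels <- list(
  sex = c("male", "female"),
  group = c("low_AQ", "high_AQ")
)

#' Validate a cohort table
#'
#' A cohort table has one row per subject: `subject_id`, `sex`
#' (male/female), optional `group` (low_AQ/high_AQ), one numeric column
#' per facial distance in mm and optionally `facial_area` in mm^2.
#'
#' @param cohort Data frame to validate.
#' @return The cohort as a tibble, invisibly usable; errors describe the
#'   first violated constraint.
#' @export
validate_cohort <- function(cohort) {
  tb <- as_tibble(cohort)
  if (nrow(tb) == 0) abort("Cohort table has no subjects.")
  if (!"subject_id" %in% names(tb)) abort("Cohort table needs a subject_id column.")
  if ("sex" %in% names(tb)) {
    bad <- setdiff(unique(tb$sex[!is.na(tb$sex)]), cohort_label_levels$sex)
    if (length(bad) > 0) {
      abort(paste0("Unknown sex label(s): ", paste(bad, collapse = ", "),
                   " (allowed: male, female)"))
    }
  }
  if ("group" %in% names(tb)) {
    bad <- setdiff(unique(tb$group[!is.na(tb$group)]), cohort_label_levels$group)
    if (length(bad) > 0) {
      abort(paste0("Unknown group label(s): ", paste(bad, collapse = ", "),
                   " (allowed: low_AQ, high_AQ)"))
    }
  }
  for (fc in cohort_feature_names(tb)) {
    v <- tb[[fc]]
    if (!is.numeric(v)) abort(paste0("Feature column '", fc, "' is not numeric."))
    if (any(!is.na(v) & v <= 0)) {
      abort(paste0("Feature column '", fc, "' contains non-positive values; distances and areas must be > 0."))
    }
  }
  tb
}

cohort_feature_names <- function(cohort) {
  setdiff(names(cohort), c("subject_id", "sex", "group"))
}

#' Read / write a cohort CSV
#'
#' The on-disk layout is a plain CSV with header
#' `subject_id,sex[,group],<distance columns...>[,facial_area]`. Values
#' round-trip to at least six significant digits; labels exactly.
#'
#' @param path CSV path.
#' @return `read_cohort()` returns a validated tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("Cohort file not found: ", path))
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(tb)
}

#' @param cohort Cohort tibble (see [validate_cohort()]).
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  tb <- validate_cohort(cohort)
  readr::write_csv(tb, path)
  invisible(path)
}
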