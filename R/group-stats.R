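#' Pooled two-sample t-test from summary statistics
#'
#' Equal-variance (pooled) independent-samples t-test computed directly
#' from group means, SDs and sizes, with the variance-explained effect
#' size `r^2 = t^2 / (t^2 + df)`. Published tables report exactly these
#' moments, so every printed t and r-squared can be reproduced without
#' raw data. The pooled (not Welch) form is used throughout: reported
#' degrees of freedom equal `n1 + n2 - 2`, which identifies it.
#'
#' @param m1,sd1,n1 Mean, SD (> 0) and size (>= 2) of group 1.
#' @param m2,sd2,n2 Same for group 2.
#' @param feature Optional feature name carried into the result.
#' @return One-row tibble: `feature`, `t`, `df`, `p` (two-tailed), `r2`,
#'   and the echoed group moments.
#' @export
#' @examples
#' summary_t_test(124.12, 5.27, 107, 113.41, 5.53, 101)  # t = 14.30
summary_t_test <- function(m1, sd1, n1, m2, sd2, n2, feature = NA_character_) {
  if (sd1 <= 0 || sd2 <= 0) abort("Group SDs must be strictly positive.")
  if (n1 < 2 || n2 < 2) abort("Group sizes must be >= 2.")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(t), df)
  tibble(
    feature = feature, t = t, df = as.integer(df), p = p,
    r2 = t^2 / (t^2 + df),
    m1 = m1, sd1 = sd1, n1 = as.integer(n1),
    m2 = m2, sd2 = sd2, n2 = as.integer(n2)
  )
}

#' Per-feature pooled t-tests on a cohort
#'
#' Splits the cohort by a two-level grouping column and applies
#' [summary_t_test()] to each feature's per-group sample moments, so the
#' raw-data and summary-statistic paths agree to machine precision.
#' Group 1 is `reference` (defaults to the alphabetically first level);
#' positive t means the reference group mean is larger.
#'
#' @param cohort Cohort tibble.
#' @param features Feature columns to test (default: all).
#' @param grouping Grouping column (`"sex"` or `"group"`).
#' @param reference Level treated as group 1.
#' @return Tibble with one [summary_t_test()] row per feature.
#' @export
cohort_t_tests <- function(cohort, features = NULL, grouping = "sex",
                           reference = NULL) {
  tb <- as_tibble(cohort)
  if (!grouping %in% names(tb)) abort(paste0("Grouping column '", grouping, "' not found."))
  labels <- as.character(tb[[grouping]])
  lv <- sort(unique(labels))
  if (length(lv) != 2) abort("Grouping column must have exactly 2 levels.")
  if (is.null(reference)) reference <- lv[1]
  if (!reference %in% lv) abort("reference level not present in grouping column.")
  other <- setdiff(lv, reference)
  if (is.null(features)) features <- cohort_feature_names(tb)
  i1 <- labels == reference; i2 <- labels == other
  if (sum(i1) < 2 || sum(i2) < 2) abort("Each group needs >= 2 subjects.")
  list_rbind(map(features, function(f) {
    x1 <- tb[[f]][i1]; x2 <- tb[[f]][i2]
    summary_t_test(mean(x1), sd(x1), sum(i1), mean(x2), sd(x2), sum(i2),
                   feature = f)
  }))
}

#' Classify the direction of a trait-group facial shift
#'
#' Given, per feature, a sex-reference comparison (male minus female, the
#' dimorphism direction) and a high- vs low-trait comparison within one
#' sex, decides whether the high-trait group's faces moved toward or away
#' from that sex's typical morphology. For males, a significant shift
#' opposite the male-female difference (e.g. smaller male-larger
#' distances) is `less_sex_typical` (less masculine); a shift along it is
#' `more_sex_typical`. For females the reading inverts: moving toward
#' male-typical values is `less_sex_typical`, away from them
#' `more_sex_typical`. Non-significant comparisons are `null`.
#'
#' @param sex_reference Tibble from [cohort_t_tests()] or
#'   [summary_t_test()] comparing male (group 1) vs female per feature.
#' @param trait_result Same-feature tibble comparing high-AQ (group 1) vs
#'   low-AQ within one sex.
#' @param sex `"male"` or `"female"`: which sex `trait_result` describes.
#' @param alpha Significance level for the trait comparison (default .05).
#' @return Tibble: `feature`, `sex`, `direction`
#'   (`less_sex_typical`/`more_sex_typical`/`null`), `trait_shift` and
#'   `dimorphism` (signs), `p`.
#' @export
call_dimorphism_direction <- function(sex_reference, trait_result,
                                      sex = c("male", "female"), alpha = 0.05) {
  sex <- arg_match(sex)
  extra <- setdiff(trait_result$feature, sex_reference$feature)
  if (length(extra) > 0) {
    abort(paste0("Feature(s) missing from sex reference: ", paste(extra, collapse = ", ")))
  }
  common <- intersect(sex_reference$feature, trait_result$feature)
  if (length(common) == 0) abort("No shared features between the two result tables.")
  ref <- sex_reference[match(common, sex_reference$feature), ]
  tr <- trait_result[match(common, trait_result$feature), ]
  dimorphism <- sign(ref$m1 - ref$m2)      # + when male-larger
  shift <- sign(tr$m1 - tr$m2)             # + when high-trait larger
  masculinisation <- shift * dimorphism    # + when shifted toward male-typical
  direction <- dplyr::case_when(
    tr$p >= alpha ~ "null",
    sex == "male" & masculinisation < 0 ~ "less_sex_typical",
    sex == "male" & masculinisation > 0 ~ "more_sex_typical",
    sex == "female" & masculinisation > 0 ~ "less_sex_typical",
    sex == "female" & masculinisation < 0 ~ "more_sex_typical",
    .default = "null"
  )
  tibble(feature = common, sex = sex, direction = direction,
         trait_shift = shift, dimorphism = dimorphism, p = tr$p)
}
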