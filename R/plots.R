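#' Plot per-feature group effect sizes
#'
#' Bar chart of r-squared effect sizes from a table of pooled t-tests,
#' annotated with significance at `alpha`.
#'
#' @param t_tests Tibble from [cohort_t_tests()] or [summary_t_test()].
#' @param alpha Significance level used for the fill aesthetic.
#' @return A ggplot object.
#' @export
plot_effect_sizes <- function(t_tests, alpha = 0.05) {
  df <- dplyr::mutate(t_tests, significant = .data$p < alpha)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$r2),
    y = .data$r2, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(r^2 ~ "effect size"),
                  fill = sprintf("p < %.2g", alpha)) +
    ggplot2::theme_minimal()
}

#' Gender-score distributions of a fitted discriminant
#'
#' Histograms of the continuous gender score by true class, with the
#' decision boundary at zero.
#'
#' @param object A [fit_lda()] model.
#' @param cohort Cohort to score (typically the training cohort).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot facedim_lda
#' @export
autoplot.facedim_lda <- function(object, cohort, ...) {
  tb <- as_tibble(cohort)
  df <- tibble(score = gender_score(object, tb),
               class = as.character(tb[[object$label_column]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$class)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 40) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "gender score (signed distance from hyperplane)",
                  y = "subjects") +
    ggplot2::theme_minimal()
}

#' Standardized-coefficient profile of a discriminant function analysis
#'
#' Bars of standardized coefficients with the conventional |.30|
#' significant-predictor band.
#'
#' @param object A [fit_dfa()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot facedim_dfa
#' @export
autoplot.facedim_dfa <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$feature, abs(.data$standardized_coefficient)),
    y = .data$standardized_coefficient, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-0.3, 0.3), linetype = "dotted") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "standardized coefficient") +
    ggplot2::theme_minimal()
}

#' Accuracy of nested feature-subset prefixes
#'
#' Line plot of the cross-validated accuracy path explored by
#' [select_optimal_subset()].
#'
#' @param selection Result of [select_optimal_subset()].
#' @return A ggplot object.
#' @export
plot_selection_path <- function(selection) {
  ggplot2::ggplot(selection$path, ggplot2::aes(
    x = .data$size, y = .data$mean_per_class_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = length(selection$features),
                        linetype = "dashed") +
    ggplot2::labs(x = "ranking prefix size",
                  y = "mean per-class CV accuracy (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
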