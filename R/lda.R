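resolve_two_classes <- function(labels, positive_class = NULL) {
  cls <- sort(unique(as.character(labels)))
  if (length(cls) != 2) {
    abort(sprintf("Two-class discriminant needs exactly 2 classes, got %d.", length(cls)))
  }
  if (is.null(positive_class)) {
    positive_class <- if ("male" %in% cls) "male"
    else if ("high_AQ" %in% cls) "high_AQ"
    else cls[1]
  }
  if (!positive_class %in% cls) abort("positive_class not present in labels.")
  c(positive_class, setdiff(cls, positive_class))
}

#' Fit a two-class linear discriminant (gender-score) model
#'
#' Classical Fisher/Gaussian linear discriminant, implemented directly:
#' the weight vector solves `S_pooled w = mu_pos - mu_neg` where
#' `S_pooled` is the pooled within-class covariance, and the decision
#' threshold is the midpoint of the projected class means shifted by the
#' log prior ratio. For male/female cohorts the signed distance from the
#' decision hyperplane is the continuous gender score: positive scores
#' read as male, negative as female.
#'
#' @param cohort Cohort tibble.
#' @param features Feature columns to use.
#' @param label_column Class-label column (default `"sex"`).
#' @param positive_class Class mapped to positive scores; defaults to
#'   `"male"`/`"high_AQ"` when present, else the alphabetically first
#'   class.
#' @param priors `"equal"` (default) or `"proportional"` to the training
#'   class frequencies.
#' @return A `facedim_lda` model object.
#' @export
fit_lda <- function(cohort, features, label_column = "sex",
                    positive_class = NULL, priors = c("equal", "proportional")) {
  priors <- arg_match(priors)
  tb <- as_tibble(cohort)
  missing_f <- setdiff(features, names(tb))
  if (length(missing_f) > 0) {
    abort(paste0("Feature(s) not in cohort: ", paste(missing_f, collapse = ", ")))
  }
  labels <- as.character(tb[[label_column]])
  classes <- resolve_two_classes(labels, positive_class)
  X <- as.matrix(tb[, features, drop = FALSE])
  if (!all(is.finite(X))) abort("Features contain non-finite values.")
  n_by <- table(factor(labels, levels = classes))
  if (any(n_by < 2)) abort("Each class needs at least 2 samples.")

  mu <- rbind(colMeans(X[labels == classes[1], , drop = FALSE]),
              colMeans(X[labels == classes[2], , drop = FALSE]))
  rownames(mu) <- classes
  S1 <- cov(X[labels == classes[1], , drop = FALSE])
  S0 <- cov(X[labels == classes[2], , drop = FALSE])
  n <- nrow(X); p <- length(features)
  Sp <- ((n_by[1] - 1) * S1 + (n_by[2] - 1) * S0) / (n - 2)

  regularized <- FALSE
  ok <- tryCatch({chol(Sp); TRUE}, error = function(e) FALSE)
  if (!ok || rcond(Sp) < 1e-12) {
    lambda <- 1e-6 * sum(diag(Sp)) / p
    Sp <- Sp + diag(lambda, p)
    regularized <- TRUE
    warn(sprintf("Pooled covariance singular or ill-conditioned; ridge lambda = %.3g added.", lambda))
  }

  w <- drop(solve(Sp, mu[1, ] - mu[2, ]))
  pri <- if (priors == "equal") c(0.5, 0.5) else as.numeric(n_by) / n
  proj <- drop(mu %*% w)
  threshold <- mean(proj) - log(pri[1] / pri[2])

  structure(list(
    features = features, classes = classes, class_means = mu,
    pooled_cov = Sp, weights = setNames(w, features),
    threshold = threshold, priors = setNames(pri, classes),
    n = setNames(as.integer(n_by), classes), regularized = regularized,
    label_column = label_column
  ), class = "facedim_lda")
}

#' @export
print.facedim_lda <- function(x, ...) {
  cat(sprintf("<facedim_lda> %s vs %s on %d feature(s); n = %d + %d\n",
              x$classes[1], x$classes[2], length(x$features), x$n[1], x$n[2]))
  invisible(x)
}

feature_row_matrix <- function(model, newdata) {
  if (is.numeric(newdata) && !is.null(names(newdata))) {
    newdata <- as_tibble(as.list(newdata))
  }
  tb <- as_tibble(newdata)
  missing_f <- setdiff(model$features, names(tb))
  if (length(missing_f) > 0) {
    abort(paste0("Missing model feature(s): ", paste(missing_f, collapse = ", ")))
  }
  as.matrix(tb[, model$features, drop = FALSE])
}

#' Continuous gender score of one or more faces
#'
#' Signed distance (in discriminant units) of a feature vector from the
#' fitted decision hyperplane: `w' x - threshold`. Positive scores are
#' classified as the model's positive class (male for sex models).
#'
#' @param model A [fit_lda()] model.
#' @param newdata Named numeric vector, or data frame with the model's
#'   feature columns.
#' @return Numeric vector of scores.
#' @export
gender_score <- function(model, newdata) {
  stopifnot(inherits(model, "facedim_lda"))
  X <- feature_row_matrix(model, newdata)
  drop(X %*% model$weights) - model$threshold
}

#' Predict classes from a fitted two-class discriminant
#'
#' @param object A `facedim_lda` model.
#' @param newdata Data frame with the model's feature columns.
#' @param ... Unused.
#' @return Tibble with `score` and `class`.
#' @export
predict.facedim_lda <- function(object, newdata, ...) {
  s <- gender_score(object, newdata)
  tibble(score = s,
         class = ifelse(s > 0, object$classes[1], object$classes[2]))
}

#' @method tidy facedim_lda
#' @export
tidy.facedim_lda <- function(x, ...) {
  tibble(feature = x$features, weight = unname(x$weights),
         mean_positive = x$class_means[1, ], mean_negative = x$class_means[2, ])
}

#' @method glance facedim_lda
#' @export
glance.facedim_lda <- function(x, ...) {
  tibble(positive_class = x$classes[1], negative_class = x$classes[2],
         n_features = length(x$features), n = sum(x$n),
         threshold = x$threshold, regularized = x$regularized)
}

stratified_folds <- function(labels, folds, seed) {
  if (folds < 2) abort("folds must be >= 2.")
  if (folds > min(table(labels))) {
    abort("folds exceeds the smallest class size; stratification impossible.")
  }
  assignment <- integer(length(labels))
  set.seed(seed)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    assignment[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

#' Stratified k-fold cross-validation of the linear discriminant
#'
#' Folds are stratified by class via a seeded shuffle; every sample is
#' predicted exactly once by a model that never saw it. Accuracy is
#' reported per class from the pooled out-of-fold predictions (per-fold
#' averages are also returned for comparison).
#'
#' @inheritParams fit_lda
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle (default 20150415).
#' @return List with `per_class` (tibble: class, n, correct, accuracy %),
#'   `overall` (%), `fold_accuracy` (per-fold overall %), `confusion`
#'   (table) and `predictions` (tibble with fold, truth, score, class).
#' @export
cross_validate_lda <- function(cohort, features, label_column = "sex",
                               folds = 10, seed = 20150415,
                               positive_class = NULL,
                               priors = c("equal", "proportional")) {
  priors <- arg_match(priors)
  tb <- as_tibble(cohort)
  labels <- as.character(tb[[label_column]])
  classes <- resolve_two_classes(labels, positive_class)
  fold_id <- stratified_folds(labels, folds, seed)

  preds <- map(seq_len(folds), function(f) {
    train <- tb[fold_id != f, , drop = FALSE]
    test <- tb[fold_id == f, , drop = FALSE]
    model <- fit_lda(train, features, label_column,
                     positive_class = classes[1], priors = priors)
    pr <- predict(model, test)
    tibble(fold = f, truth = labels[fold_id == f],
           score = pr$score, class = pr$class)
  })
  preds <- list_rbind(preds)

  per_class <- preds %>%
    group_by(.data$truth) %>%
    summarise(n = n(), correct = sum(.data$class == .data$truth),
              accuracy = 100 * mean(.data$class == .data$truth),
              .groups = "drop") %>%
    dplyr::rename(class = "truth") %>%
    arrange(match(.data$class, classes))
  list(
    per_class = per_class,
    overall = 100 * mean(preds$class == preds$truth),
    fold_accuracy = preds %>% group_by(.data$fold) %>%
      summarise(accuracy = 100 * mean(.data$class == .data$truth), .groups = "drop"),
    confusion = table(truth = preds$truth, predicted = preds$class),
    predictions = preds
  )
}
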