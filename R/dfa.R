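dfa_scatter <- function(X, labels, classes) {
  mu_all <- colMeans(X)
  W <- matrix(0, ncol(X), ncol(X)); B <- W
  for (cl in classes) {
    Xi <- X[labels == cl, , drop = FALSE]
    mi <- colMeans(Xi)
    Ci <- sweep(Xi, 2, mi)
    W <- W + crossprod(Ci)
    B <- B + nrow(Xi) * tcrossprod(mi - mu_all)
  }
  list(W = W, B = B)
}

dfa_classify <- function(X, v, centroids, priors) {
  # two-group Gaussian rule on the 1-D canonical variate (unit
  # within-group variance by construction): assign group 1 when
  # (proj - midpoint) * sign(c1 - c2) > -log(pi1/pi0) / |c1 - c2|
  proj <- drop(X %*% v)
  mid <- mean(centroids)
  s <- sign(centroids[1] - centroids[2])
  shift <- log(priors[1] / priors[2]) / abs(centroids[1] - centroids[2])
  ifelse((proj - mid) * s + shift > 0, 1L, 2L)
}

#' Two-group discriminant function analysis
#'
#' Canonical discriminant analysis for two groups: the discriminant
#' weights are the leading eigenvector of `W^-1 B` (within- and
#' between-group scatter), scaled so the canonical variate has unit
#' pooled within-group variance and oriented so the positive class
#' centroid projects positive. Reports standardized coefficients
#' (`raw_i * sqrt(W_ii / (n - g))`), Wilks' lambda with Bartlett's
#' chi-square significance test, resubstitution classification accuracy
#' and leave-one-out cross-validated accuracy under the Fisher rule.
#'
#' @param cohort Cohort tibble.
#' @param features Feature columns entered into the analysis.
#' @param group_column Two-level grouping column (default `"group"`).
#' @param positive_class Group whose centroid projects positive
#'   (defaults to `"high_AQ"` when present).
#' @param priors `"equal"` (default) or `"proportional"`.
#' @param cv Run leave-one-out cross-validation (default TRUE; refits n
#'   times).
#' @return A `facedim_dfa` object; see [tidy.facedim_dfa()] and
#'   [glance.facedim_dfa()].
#' @export
fit_dfa <- function(cohort, features, group_column = "group",
                    positive_class = NULL, priors = c("equal", "proportional"),
                    cv = TRUE) {
  priors <- arg_match(priors)
  tb <- as_tibble(cohort)
  missing_f <- setdiff(features, names(tb))
  if (length(missing_f) > 0) {
    abort(paste0("Feature(s) not in cohort: ", paste(missing_f, collapse = ", ")))
  }
  labels <- as.character(tb[[group_column]])
  classes <- resolve_two_classes(labels, positive_class)
  X <- as.matrix(tb[, features, drop = FALSE])
  n <- nrow(X); p <- ncol(X); g <- 2L
  n_by <- table(factor(labels, levels = classes))
  if (any(n_by <= p)) {
    abort("Each group must have more subjects than features; drop features or regularise.")
  }

  sc <- dfa_scatter(X, labels, classes)
  W <- sc$W; B <- sc$B
  ev <- eigen(solve(W, B))
  v <- Re(ev$vectors[, which.max(Re(ev$values))])
  # unit pooled within-group variance of the canonical variate
  v <- v / sqrt(drop(t(v) %*% (W / (n - g)) %*% v))
  mu <- rbind(colMeans(X[labels == classes[1], , drop = FALSE]),
              colMeans(X[labels == classes[2], , drop = FALSE]))
  if (drop((mu[1, ] - mu[2, ]) %*% v) < 0) v <- -v

  wilks <- det(W) / det(W + B)
  chi_sq <- -(n - 1 - (p + g) / 2) * log(wilks)
  chi_df <- p * (g - 1)
  p_value <- pchisq(chi_sq, chi_df, lower.tail = FALSE)
  standardized <- v * sqrt(diag(W) / (n - g))

  pri <- if (priors == "equal") c(0.5, 0.5) else as.numeric(n_by) / n
  centroids <- drop(mu %*% v)
  pred <- dfa_classify(X, v, centroids, pri)
  truth <- match(labels, classes)
  resub <- 100 * mean(pred == truth)

  cv_acc <- NA_real_
  if (cv) {
    hits <- vapply(seq_len(n), function(i) {
      li <- labels[-i]
      sci <- dfa_scatter(X[-i, , drop = FALSE], li, classes)
      vi <- Re(eigen(solve(sci$W, sci$B))$vectors[, 1])
      mui <- rbind(colMeans(X[-i, , drop = FALSE][li == classes[1], , drop = FALSE]),
                   colMeans(X[-i, , drop = FALSE][li == classes[2], , drop = FALSE]))
      if (drop((mui[1, ] - mui[2, ]) %*% vi) < 0) vi <- -vi
      vi <- vi / sqrt(drop(t(vi) %*% (sci$W / (n - 1 - g)) %*% vi))
      pri_i <- if (priors == "equal") c(0.5, 0.5) else
        as.numeric(table(factor(li, levels = classes))) / (n - 1)
      ci <- drop(mui %*% vi)
      dfa_classify(X[i, , drop = FALSE], vi, ci, pri_i) == truth[i]
    }, logical(1))
    cv_acc <- 100 * mean(hits)
  }

  structure(list(
    features = features, classes = classes, n = setNames(as.integer(n_by), classes),
    raw_coefficients = setNames(v, features),
    standardized_coefficients = setNames(standardized, features),
    centroids = setNames(centroids, classes),
    wilks_lambda = wilks, chi_square = chi_sq, chi_df = chi_df, p = p_value,
    classification_accuracy = resub, cv_accuracy = cv_acc,
    priors = setNames(pri, classes), group_column = group_column
  ), class = "facedim_dfa")
}

#' @export
print.facedim_dfa <- function(x, ...) {
  cat(sprintf(
    "<facedim_dfa> %s vs %s | Wilks' lambda = %.3f, chi2(%d) = %.1f, p = %.3g\n",
    x$classes[1], x$classes[2], x$wilks_lambda, x$chi_df, x$chi_square, x$p))
  cat(sprintf("  classified %.1f%% (leave-one-out %.1f%%)\n",
              x$classification_accuracy, x$cv_accuracy))
  invisible(x)
}

#' Predictors whose standardized coefficient passes a magnitude rule
#'
#' Flags features with `|standardized coefficient| > threshold` (strictly
#' greater; the conventional cut-off is .30). Signs are preserved in the
#' returned table so suppressor-like negative contributions stay visible.
#'
#' @param result A `facedim_dfa` fit.
#' @param threshold Absolute-value cut-off (default 0.30).
#' @return Tibble of flagged features with their standardized
#'   coefficients, ordered as entered.
#' @export
flag_significant_predictors <- function(result, threshold = 0.30) {
  stopifnot(inherits(result, "facedim_dfa"))
  sc <- result$standardized_coefficients
  keep <- abs(sc) > threshold
  tibble(feature = names(sc)[keep], standardized_coefficient = unname(sc[keep]))
}

#' Tidy a discriminant function analysis
#'
#' @param x A `facedim_dfa` fit.
#' @param ... Unused.
#' @return Tibble: `feature`, `raw_coefficient`,
#'   `standardized_coefficient`, `significant` (|std| > .30).
#' @method tidy facedim_dfa
#' @export
tidy.facedim_dfa <- function(x, ...) {
  tibble(feature = x$features,
         raw_coefficient = unname(x$raw_coefficients),
         standardized_coefficient = unname(x$standardized_coefficients),
         significant = abs(x$standardized_coefficients) > 0.30)
}

#' One-row summary of a discriminant function analysis
#'
#' @param x A `facedim_dfa` fit.
#' @param ... Unused.
#' @return Tibble with Wilks' lambda, Bartlett chi-square and df, p, and
#'   the resubstitution / leave-one-out accuracies (%).
#' @method glance facedim_dfa
#' @export
glance.facedim_dfa <- function(x, ...) {
  tibble(wilks_lambda = x$wilks_lambda, chi_square = x$chi_square,
         chi_df = x$chi_df, p = x$p,
         classification_accuracy = x$classification_accuracy,
         cv_accuracy = x$cv_accuracy, n = sum(x$n))
}

#' Predict group membership from a fitted DFA
#'
#' @param object A `facedim_dfa` fit.
#' @param newdata Data frame with the model's feature columns.
#' @param ... Unused.
#' @return Tibble with the canonical `score` and predicted `class`.
#' @export
predict.facedim_dfa <- function(object, newdata, ...) {
  tb <- as_tibble(newdata)
  missing_f <- setdiff(object$features, names(tb))
  if (length(missing_f) > 0) {
    abort(paste0("Missing model feature(s): ", paste(missing_f, collapse = ", ")))
  }
  X <- as.matrix(tb[, object$features, drop = FALSE])
  idx <- dfa_classify(X, object$raw_coefficients, object$centroids, object$priors)
  tibble(score = drop(X %*% object$raw_coefficients) - mean(object$centroids),
         class = object$classes[idx])
}
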