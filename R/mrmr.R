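#' Equal-frequency discretisation
#'
#' Cuts a numeric vector into (up to) `bins` levels at its empirical
#' quantiles. Because the breaks are quantiles, any strictly monotone
#' rescaling of the input yields the same level assignment, which makes
#' the downstream mutual-information estimates scale-free.
#'
#' @param x Numeric vector.
#' @param bins Target number of levels.
#' @return Integer vector of level codes.
#' @keywords internal
discretize_ef <- function(x, bins = 8) {
  brks <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                          type = 7, names = FALSE))
  if (length(brks) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = brks, include.lowest = TRUE))
}

#' Mutual information between a numeric feature and class labels
#'
#' Plug-in (maximum-likelihood) estimate from the joint histogram of the
#' equal-frequency-discretised feature against the labels, in bits.
#' Bounded by both `log2(bins)` and the label entropy.
#'
#' @param x Numeric feature values.
#' @param labels Class labels (any discrete vector, >= 2 classes).
#' @param bins Number of equal-frequency bins (default 8).
#' @return Mutual information in bits.
#' @export
#' @examples
#' lab <- rep(c("a", "b"), each = 100)
#' mutual_information(ifelse(lab == "a", 0, 1), lab)  # 1 bit
mutual_information <- function(x, labels, bins = 8) {
  if (length(x) != length(labels)) abort("x and labels must have equal length.")
  if (length(x) < 2) abort("Need at least 2 samples.")
  if (length(unique(labels)) < 2) abort("Need at least 2 classes in labels.")
  if (length(unique(x)) == 1) {
    warn("Constant feature: mutual information is 0.")
    return(0)
  }
  xd <- discretize_ef(x, bins)
  joint <- table(xd, labels) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

# pairwise MI between two numeric features, both discretised
mutual_information_ff <- function(x, y, bins = 8) {
  xd <- discretize_ef(x, bins); yd <- discretize_ef(y, bins)
  joint <- table(xd, yd) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

#' Rank features by minimal-redundancy maximal-relevance
#'
#' Greedy forward selection: the first feature maximises mutual
#' information with the class label (relevance); each subsequent step
#' maximises, over unselected features, relevance minus the mean mutual
#' information with the already-selected set (MID difference criterion) or
#' relevance divided by it (MIQ quotient, `variant = "MIQ"`). Ties break
#' by alphabetical feature name, so the ranking is fully deterministic.
#'
#' @param cohort Cohort tibble.
#' @param label_column Name of the class-label column (e.g. `"sex"`).
#' @param features Feature columns to rank (default: all numeric feature
#'   columns).
#' @param k How many features to rank (default all).
#' @param bins Discretisation bins for the MI estimator.
#' @param variant `"MID"` (difference, default) or `"MIQ"` (quotient).
#' @return An object of class `mrmr_result`: tibble with columns `rank`,
#'   `feature`, `score` (criterion value at selection) and `relevance`
#'   (MI with the label, bits); `params` attribute records settings.
#' @export
mrmr_rank <- function(cohort, label_column = "sex", features = NULL,
                      k = NULL, bins = 8, variant = c("MID", "MIQ")) {
  variant <- arg_match(variant)
  tb <- as_tibble(cohort)
  if (!label_column %in% names(tb)) {
    abort(paste0("Label column '", label_column, "' not found in cohort."))
  }
  if (is.null(features)) features <- cohort_feature_names(tb)
  features <- sort(features)
  if (is.null(k)) k <- length(features)
  if (k < 1) abort("k must be >= 1.")
  if (k > length(features)) abort("k exceeds the number of features.")
  labels <- tb[[label_column]]

  relevance <- map_dbl(set_names(features), function(f) {
    mutual_information(tb[[f]], labels, bins = bins)
  })
  # symmetric feature-feature MI, computed lazily
  red_cache <- matrix(NA_real_, length(features), length(features),
                      dimnames = list(features, features))
  redundancy <- function(f, g) {
    if (is.na(red_cache[f, g])) {
      m <- mutual_information_ff(tb[[f]], tb[[g]], bins = bins)
      red_cache[f, g] <<- m; red_cache[g, f] <<- m
    }
    red_cache[f, g]
  }

  selected <- character(0)
  scores <- numeric(0)
  remaining <- features
  for (step in seq_len(k)) {
    crit <- map_dbl(set_names(remaining), function(f) {
      if (length(selected) == 0) return(relevance[[f]])
      red <- mean(map_dbl(selected, function(s) redundancy(f, s)))
      if (variant == "MID") relevance[[f]] - red
      else relevance[[f]] / (red + 1e-12)
    })
    best <- names(crit)[order(-crit, names(crit))][1]  # ties: alphabetical
    selected <- c(selected, best)
    scores <- c(scores, crit[[best]])
    remaining <- setdiff(remaining, best)
  }
  structure(
    tibble(rank = seq_along(selected), feature = selected, score = scores,
           relevance = unname(relevance[selected])),
    params = list(bins = bins, variant = variant, label_column = label_column),
    class = c("mrmr_result", class(tibble())))
}

#' Select the optimal feature subset by cross-validated LDA
#'
#' Evaluates nested prefixes of an mRMR ranking with stratified k-fold
#' cross-validated linear discriminant analysis and returns the prefix
#' maximising mean per-class accuracy; exact ties go to the smaller
#' subset. An exhaustive search over all subsets is intractable and is
#' not attempted; prefix search over the mRMR order is the standard
#' practice.
#'
#' @param cohort Cohort tibble.
#' @param ranking An `mrmr_result` from [mrmr_rank()].
#' @param label_column Class-label column.
#' @param folds Cross-validation folds (default 10).
#' @param seed Seed for the fold shuffle.
#' @param max_size Largest prefix to evaluate (default: full ranking).
#' @return List with `features` (selected subset, in ranking order),
#'   `accuracy` (per-class and overall, from [cross_validate_lda()]), and
#'   `path`: tibble of prefix size vs mean per-class accuracy.
#' @export
select_optimal_subset <- function(cohort, ranking, label_column = "sex",
                                  folds = 10, seed = 20150415,
                                  max_size = NULL) {
  stopifnot(inherits(ranking, "mrmr_result"))
  feats <- ranking$feature
  if (is.null(max_size)) max_size <- length(feats)
  sizes <- seq_len(min(max_size, length(feats)))
  evals <- map(sizes, function(m) {
    cross_validate_lda(cohort, features = feats[seq_len(m)],
                       label_column = label_column, folds = folds, seed = seed)
  })
  path <- tibble(
    size = sizes,
    mean_per_class_accuracy = map_dbl(evals, function(e) mean(e$per_class$accuracy)),
    overall_accuracy = map_dbl(evals, function(e) e$overall)
  )
  best <- which.max(path$mean_per_class_accuracy)  # which.max takes first tie
  list(
    features = feats[seq_len(best)],
    accuracy = evals[[best]],
    path = path
  )
}
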