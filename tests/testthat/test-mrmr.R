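test_that("mutual information matches closed forms and bounds", {
  lab <- rep(c("a", "b"), each = 500)
  x <- ifelse(lab == "a", 0, 1) + rep(seq(0, 1e-6, length.out = 500), 2)
  expect_equal(mutual_information(x, lab), 1, tolerance = 1e-9)

  set.seed(4)
  xi <- rnorm(10000)
  li <- sample(c("a", "b"), 10000, replace = TRUE)
  expect_lt(mutual_information(xi, li), 0.02)

  expect_warning(mi0 <- mutual_information(rep(3, 100), rep(c("a", "b"), 50)),
                 "Constant")
  expect_equal(mi0, 0)
  expect_error(mutual_information(1:5, rep("a", 5)), "2 classes")
})

test_that("the estimator agrees with an independent joint-histogram oracle", {
  set.seed(8)
  x <- rnorm(400); lab <- rep(c("m", "f"), each = 200)
  brks <- unique(quantile(x, seq(0, 1, length.out = 9), names = FALSE))
  xd <- cut(x, brks, include.lowest = TRUE)
  expect_equal(mutual_information(x, lab, bins = 8), mi_oracle_bits(xd, lab),
               tolerance = 1e-12)
})

test_that("MI is invariant to monotone rescaling under quantile binning", {
  set.seed(5)
  x <- rlnorm(1000); lab <- rep(c("a", "b"), 500)
  expect_equal(mutual_information(x, lab), mutual_information(log(x), lab))
  expect_equal(mutual_information(x, lab), mutual_information(x^3, lab))
})

test_that("mRMR rejects a redundant copy in favour of complementary noise", {
  set.seed(2)
  n <- 1000
  lab <- rep(c("a", "b"), each = n / 2)
  A <- ifelse(lab == "a", 0, 1) + rnorm(n, sd = 0.05)
  cohort <- tibble::tibble(
    subject_id = as.character(seq_len(n)), label = lab,
    A = A + 10, B = A + rnorm(n, sd = 0.01) + 10, C = rnorm(n) + 10)
  rk <- mrmr_rank(cohort, label_column = "label", features = c("A", "B", "C"),
                  k = 2)
  expect_equal(rk$feature[1], "A")
  expect_equal(rk$feature[2], "C")  # B rejected as redundant with A
  expect_true(all(is.finite(rk$score)))
})

test_that("k = 1 reduces to the relevance argmax and ranking is a permutation", {
  coh <- generate_distance_cohort(study1_spec(seed = 6))
  feats <- setdiff(names(coh), c("subject_id", "sex", "group"))
  rk1 <- mrmr_rank(coh, k = 1)
  rel <- vapply(setNames(sort(feats), sort(feats)),
                function(f) mutual_information(coh[[f]], coh$sex), numeric(1))
  expect_equal(rk1$feature, names(which.max(rel)))
  rk <- mrmr_rank(coh)
  expect_setequal(rk$feature, feats)
  expect_error(mrmr_rank(coh, k = 0), "k must be")
  expect_error(mrmr_rank(coh, k = 99), "exceeds")
})

test_that("greedy selection equals per-step brute force over all candidates", {
  coh <- generate_distance_cohort(study1_spec(seed = 13))
  feats <- sort(c(six_dimorphic))
  rk <- mrmr_rank(coh, features = feats, k = 3, bins = 8)

  # independent re-derivation: at each step score every candidate from scratch
  mi_ef <- function(x, y, bins = 8) {
    dis <- function(v) {
      b <- unique(quantile(v, seq(0, 1, length.out = bins + 1), names = FALSE))
      if (length(b) < 2) rep(1, length(v)) else cut(v, b, include.lowest = TRUE)
    }
    xd <- if (is.numeric(x)) dis(x) else x
    yd <- if (is.numeric(y)) dis(y) else y
    mi_oracle_bits(xd, yd)
  }
  sel <- character(0)
  for (step in 1:3) {
    cand <- setdiff(feats, sel)
    crit <- vapply(cand, function(f) {
      rel <- mi_ef(coh[[f]], coh$sex)
      if (length(sel) == 0) rel
      else rel - mean(vapply(sel, function(s) mi_ef(coh[[f]], coh[[s]]), numeric(1)))
    }, numeric(1))
    sel <- c(sel, cand[order(-crit, cand)][1])
  }
  expect_equal(rk$feature, sel)
})

test_that("rankings are deterministic and MIQ is available", {
  coh <- generate_distance_cohort(study1_spec(seed = 21))
  expect_identical(mrmr_rank(coh), mrmr_rank(coh))
  rq <- mrmr_rank(coh, variant = "MIQ")
  expect_setequal(rq$feature, mrmr_rank(coh)$feature)
})

test_that("a perfectly separating feature yields a size-1 subset at 100%", {
  set.seed(3)
  n <- 200
  lab <- rep(c("male", "female"), each = n / 2)
  coh <- tibble::tibble(
    subject_id = as.character(1:n), sex = lab,
    winner = ifelse(lab == "male", 10, 20) + runif(n),
    noise1 = runif(n) + 5, noise2 = runif(n) + 5)
  rk <- mrmr_rank(coh)
  sel <- select_optimal_subset(coh, rk, folds = 5, seed = 1)
  expect_equal(sel$features, "winner")
  expect_equal(sel$accuracy$per_class$accuracy, c(100, 100))
})

test_that("an all-noise cohort classifies at chance", {
  set.seed(10)
  n <- 2000
  coh <- tibble::tibble(
    subject_id = as.character(1:n),
    sex = rep(c("male", "female"), each = n / 2))
  for (f in paste0("noise", 1:6)) coh[[f]] <- runif(n) + 5
  cv <- cross_validate_lda(coh, paste0("noise", 1:6), folds = 10, seed = 2)
  expect_true(abs(cv$overall - 50) < 5)
})
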