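test_that("two spherical classes give the closed-form discriminant", {
  set.seed(1)
  n <- 4000
  coh <- tibble::tibble(
    subject_id = as.character(1:(2 * n)),
    sex = rep(c("male", "female"), each = n),
    f1 = c(rnorm(n, 1), rnorm(n, -1)) + 10,
    f2 = rnorm(2 * n) + 10)
  fit <- fit_lda(coh, c("f1", "f2"))
  w <- fit$weights / fit$weights[["f1"]]
  expect_equal(unname(w[["f2"]]), 0, tolerance = 0.05)
  # midpoint of class centroids scores ~0 under equal priors
  mid <- (fit$class_means[1, ] + fit$class_means[2, ]) / 2
  expect_equal(unname(gender_score(fit, mid)), 0, tolerance = 1e-10)
  expect_gt(gender_score(fit, fit$class_means[1, ]), 0)
  expect_lt(gender_score(fit, fit$class_means[2, ]), 0)
})

test_that("the univariate boundary matches the prior-shifted midpoint formula", {
  set.seed(2)
  n1 <- 300; n0 <- 100
  coh <- tibble::tibble(
    subject_id = as.character(1:(n1 + n0)),
    sex = c(rep("male", n1), rep("female", n0)),
    f1 = c(rnorm(n1, 30, 2), rnorm(n0, 24, 2)))
  fit <- fit_lda(coh, "f1", priors = "proportional")
  m1 <- mean(coh$f1[coh$sex == "male"]); m0 <- mean(coh$f1[coh$sex == "female"])
  s2 <- fit$pooled_cov[1, 1]
  boundary_oracle <- (m1 + m0) / 2 - s2 * log((n1 / (n1 + n0)) / (n0 / (n1 + n0))) / (m1 - m0)
  boundary_fit <- stats::uniroot(function(x) gender_score(fit, c(f1 = x)),
                                 c(20, 35))$root
  expect_equal(boundary_fit, boundary_oracle, tolerance = 1e-8)
})

test_that("predictions match the reference discriminant implementation", {
  coh <- generate_distance_cohort(study1_spec(seed = 5))
  feats <- setdiff(names(coh), c("subject_id", "sex", "group", "facial_area"))
  fit <- fit_lda(coh, feats)
  ours <- predict(fit, coh)$class
  ref <- MASS::lda(as.matrix(coh[, feats]), grouping = coh$sex,
                   prior = c(female = 0.5, male = 0.5))
  theirs <- as.character(predict(ref)$class)
  expect_equal(ours, theirs)
})

test_that("predictions are invariant under a common invertible affine map", {
  coh <- generate_distance_cohort(study1_spec(seed = 17))
  feats <- six_dimorphic
  base <- predict(fit_lda(coh, feats), coh)$class
  set.seed(99)
  A <- diag(6) + matrix(rnorm(36, sd = 0.1), 6)
  b <- runif(6, 100, 200)
  Xt <- sweep(as.matrix(coh[, feats]) %*% t(A), 2, -b)
  coh2 <- coh
  coh2[, feats] <- as.data.frame(Xt)
  mapped <- predict(fit_lda(coh2, feats), coh2)$class
  expect_equal(mapped, base)
})

test_that("degenerate inputs trigger the documented errors and the ridge", {
  coh <- generate_distance_cohort(study1_spec(seed = 2))
  expect_error(fit_lda(dplyr::filter(coh, sex == "male"), six_dimorphic),
               "2 classes")
  dup <- coh
  dup$copy <- dup$forehead_width  # exact collinearity -> singular pooled cov
  expect_warning(fit <- fit_lda(dup, c("forehead_width", "copy")), "ridge")
  expect_true(fit$regularized)
  fit6 <- fit_lda(coh, six_dimorphic)
  expect_error(gender_score(fit6, c(forehead_width = 120)), "nose_width")
})

test_that("stratified cross-validation is deterministic and exhaustive", {
  coh <- generate_distance_cohort(study1_spec(seed = 3))
  cv1 <- cross_validate_lda(coh, six_dimorphic, folds = 10, seed = 77)
  cv2 <- cross_validate_lda(coh, six_dimorphic, folds = 10, seed = 77)
  expect_identical(cv1$per_class, cv2$per_class)
  expect_identical(cv1$predictions$fold, cv2$predictions$fold)
  expect_equal(nrow(cv1$predictions), nrow(coh))  # each sample predicted once
  expect_equal(sort(unique(cv1$predictions$fold)), 1:10)
  cv3 <- cross_validate_lda(coh, six_dimorphic, folds = 10, seed = 78)
  expect_false(identical(cv1$predictions$score, cv3$predictions$score))
  expect_error(cross_validate_lda(coh, six_dimorphic, folds = 1), "folds")
  expect_error(cross_validate_lda(coh, six_dimorphic, folds = 200),
               "smallest class")
})

test_that("perfectly separated classes cross-validate at 100% for any seed", {
  n <- 60
  coh <- tibble::tibble(
    subject_id = as.character(1:(2 * n)),
    sex = rep(c("male", "female"), each = n),
    f1 = c(runif(n, 10, 11), runif(n, 20, 21)),
    f2 = runif(2 * n) + 3)
  for (sd_ in c(1, 1000)) {
    cv <- cross_validate_lda(coh, c("f1", "f2"), folds = 5, seed = sd_)
    expect_equal(cv$per_class$accuracy, c(100, 100))
  }
})

test_that("accuracy grows as true dimorphic features are added", {
  coh <- generate_distance_cohort(study1_spec(n_scale = 10, seed = 8))
  # order features by reference effect size, largest first
  ord <- reference_sex_t_tests() %>% dplyr::arrange(dplyr::desc(r2)) %>%
    dplyr::pull(feature)
  accs <- vapply(c(1, 3, 6), function(k) {
    cross_validate_lda(coh, ord[seq_len(k)], folds = 5, seed = 4)$overall
  }, numeric(1))
  expect_true(all(diff(accs) > 0))
})

test_that("tidy and glance expose the fitted discriminant", {
  coh <- generate_distance_cohort(study1_spec(seed = 9))
  fit <- fit_lda(coh, six_dimorphic)
  td <- generics::tidy(fit)
  expect_equal(td$feature, six_dimorphic)
  expect_true(all(c("weight", "mean_positive") %in% names(td)))
  gl <- generics::glance(fit)
  expect_equal(gl$positive_class, "male")
  expect_equal(gl$n, 208L)
})
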