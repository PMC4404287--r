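test_that("summary_t_test reproduces every published t and r2 pair", {
  rows <- printed_t_rows()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    tt <- summary_t_test(r$m1, r$sd1, r$n1, r$m2, r$sd2, r$n2, feature = r$feature)
    expect_equal(tt$t, r$t_printed, tolerance = 0.03 / r$t_printed,
                 label = sprintf("%s/%s t", r$study, r$feature))
    expect_lt(abs(tt$r2 - r$r2_printed), 0.01)
    expect_equal(tt$df, r$n1 + r$n2 - 2L)
  }
})

test_that("degenerate and symmetric cases behave as documented", {
  eq <- summary_t_test(10, 2, 20, 10, 2, 20)
  expect_equal(eq$t, 0); expect_equal(eq$p, 1); expect_equal(eq$r2, 0)
  a <- summary_t_test(12, 2, 18, 10, 3, 25)
  b <- summary_t_test(10, 3, 25, 12, 2, 18)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_equal(a$r2, b$r2)
  expect_equal(a$r2, a$t^2 / (a$t^2 + a$df), tolerance = 1e-12)
  expect_error(summary_t_test(1, 0, 10, 2, 1, 10), "positive")
  expect_error(summary_t_test(1, 1, 1, 2, 1, 10), ">= 2")
})

test_that("cohort t-tests equal summary t-tests on the sample moments", {
  coh <- generate_distance_cohort(study2_spec("female", seed = 6))
  res <- cohort_t_tests(coh, six_dimorphic, grouping = "group",
                        reference = "high_AQ")
  for (f in six_dimorphic) {
    hi <- coh[[f]][coh$group == "high_AQ"]; lo <- coh[[f]][coh$group == "low_AQ"]
    oracle <- summary_t_test(mean(hi), sd(hi), length(hi),
                             mean(lo), sd(lo), length(lo))
    got <- res[res$feature == f, ]
    expect_equal(got$t, oracle$t, tolerance = 1e-12)
    expect_equal(got$r2, oracle$r2, tolerance = 1e-12)
  }
  # and the pooled form matches stats::t.test(var.equal = TRUE)
  f <- "forehead_width"
  ref <- stats::t.test(coh[[f]][coh$group == "high_AQ"],
                       coh[[f]][coh$group == "low_AQ"], var.equal = TRUE)
  got <- res[res$feature == f, ]
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("constant separated groups drive p to zero with the right sign", {
  coh <- tibble::tibble(
    subject_id = as.character(1:20),
    group = rep(c("low_AQ", "high_AQ"), each = 10),
    f = c(rep(10, 10), rep(12, 10)) + rep(c(0, 1e-6), 10))
  res <- cohort_t_tests(coh, "f", grouping = "group", reference = "high_AQ")
  expect_lt(res$p, 1e-10)
  expect_gt(res$t, 0)  # high_AQ (reference) larger
})

test_that("type-I error is calibrated under the null", {
  set.seed(123)
  n <- 60
  pvals <- vapply(1:1000, function(i) {
    x <- rnorm(n); y <- rnorm(n)
    summary_t_test(mean(x), sd(x), n, mean(y), sd(y), n)$p
  }, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.02)
})

test_that("dimorphism direction calls follow the sex-specific logic", {
  ref <- reference_sex_t_tests()  # all six features male-larger
  mk <- function(feature, m_high, m_low, p) tibble::tibble(
    feature = feature, t = ifelse(m_high > m_low, 3, -3), df = 56L, p = p,
    r2 = .2, m1 = m_high, sd1 = 2, n1 = 25L, m2 = m_low, sd2 = 2, n2 = 33L)

  # males, high < low on a male-larger feature, significant -> less masculine
  calls <- call_dimorphism_direction(ref, mk("forehead_width", 121.11, 126.01, .002),
                                     sex = "male")
  expect_equal(calls$direction, "less_sex_typical")
  # males, high > low, significant -> hypermasculinised
  calls <- call_dimorphism_direction(ref, mk("forehead_width", 128, 126, .01),
                                     sex = "male")
  expect_equal(calls$direction, "more_sex_typical")
  # females, high > low on a male-larger feature -> less feminine
  calls <- call_dimorphism_direction(ref, mk("forehead_width", 116.53, 110.63, .001),
                                     sex = "female")
  expect_equal(calls$direction, "less_sex_typical")
  # females, high < low (more feminine) -> more sex-typical
  calls <- call_dimorphism_direction(ref, mk("nasal_bridge_length", 40.40, 43.83, .001),
                                     sex = "female")
  expect_equal(calls$direction, "more_sex_typical")
  # non-significant -> null regardless of direction
  calls <- call_dimorphism_direction(ref, mk("nose_width", 32.46, 32.81, .642),
                                     sex = "male")
  expect_equal(calls$direction, "null")
  # mismatched features error
  expect_error(call_dimorphism_direction(ref, mk("facial_area", 1, 2, .5), "male"),
               "missing from sex reference")
})
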