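# shared fixtures, built in code at test time

six_dimorphic <- c("forehead_width", "outer_canthal_width",
                   "nasal_bridge_length", "nasal_tip_protrusion",
                   "philtrum_length", "nose_width")

# the 14 published pooled t-test rows: moments in, printed t/r2 out
printed_t_rows <- function() {
  tibble::tribble(
    ~study, ~feature, ~m1, ~sd1, ~n1, ~m2, ~sd2, ~n2, ~t_printed, ~r2_printed,
    "study1", "forehead_width",        124.12, 5.27, 107, 113.41, 5.53, 101, 14.30, .50,
    "study1", "outer_canthal_width",   96.57,  4.54, 107, 94.29,  4.20, 101, 3.75,  .06,
    "study1", "nasal_bridge_length",   47.34,  3.77, 107, 42.12,  3.62, 101, 10.18, .33,
    "study1", "nasal_tip_protrusion",  19.67,  1.95, 107, 17.18,  1.94, 101, 9.24,  .29,
    "study1", "philtrum_length",       8.17,   2.44, 107, 7.25,   1.94, 101, 3.02,  .04,
    "study1", "nose_width",            32.71,  2.58, 107, 29.08,  2.35, 101, 10.59, .35,
    "study2_male", "forehead_width",       126.01, 5.74, 33, 121.11, 5.69, 25, 3.24, .16,
    "study2_male", "outer_canthal_width",  98.38,  4.38, 33, 94.26,  4.47, 25, 3.51, .18,
    "study2_male", "nasal_bridge_length",  49.37,  4.38, 33, 46.17,  3.69, 25, 2.95, .13,
    "study2_male", "nasal_tip_protrusion", 21.62,  1.94, 33, 18.65,  2.29, 25, 5.34, .34,
    "study2_female", "forehead_width",      116.53, 4.73, 21, 110.63, 5.11, 33, 4.26, .26,
    "study2_female", "outer_canthal_width", 96.59,  4.44, 21, 90.95,  3.61, 33, 5.11, .33,
    "study2_female", "nasal_bridge_length", 43.83,  3.00, 33, 40.40,  3.64, 21, 3.76, .21,
    "study2_female", "nose_width",          30.38,  2.01, 21, 28.58,  2.10, 33, 3.12, .16
  )
}

write_landmark_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("landmark,x,y,z", lines), path)
  path
}

template_landmark_csv <- function(path = tempfile(fileext = ".csv")) {
  write_landmarks(face_template(), path)
  path
}

# two well-separated spherical Gaussian classes in p dims
two_blob_cohort <- function(n = 50, p = 2, sep = 8, seed = 1,
                            labels = c("low_AQ", "high_AQ"),
                            label_column = "group") {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * p), n, p),
             matrix(rnorm(n * p, mean = sep / sqrt(p)), n, p))
  X <- X - min(X) + 1  # keep features positive for cohort validity
  colnames(X) <- paste0("f", seq_len(p))
  tb <- tibble::tibble(subject_id = sprintf("s%04d", seq_len(2 * n)))
  tb[[label_column]] <- rep(labels, each = n)
  dplyr::bind_cols(tb, tibble::as_tibble(X))
}

# independent plug-in MI oracle used against the package estimator
mi_oracle_bits <- function(xd, yd) {
  joint <- table(xd, yd) / length(xd)
  px <- rowSums(joint); py <- colSums(joint)
  tot <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (joint[i, j] > 0) tot <- tot + joint[i, j] * log2(joint[i, j] / (px[i] * py[j]))
  }
  unname(tot)
}
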