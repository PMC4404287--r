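Package: facedim
Title: Landmark-Based 3D Facial Morphometry and Sexual Dimorphism Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landmark-based 3D facial morphometrics: reading Farkas
    landmark coordinate files and triangulated face meshes, computing the 23
    classical inter-landmark distances and facial surface area, selecting
    sexually dimorphic features by minimal-redundancy maximal-relevance (mRMR)
    ranking, scoring faces with a two-class linear discriminant (gender score)
    under tenfold cross-validation, pooled two-sample t-tests with r-squared
    effect sizes from raw cohorts or printed summary statistics, and two-group
    discriminant function analysis (Wilks' lambda, standardized coefficients,
    leave-one-out classification). Includes a seeded synthetic cohort generator
    that emulates published group means and standard deviations so the whole
    pipeline is testable without access to raw 3D face scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
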