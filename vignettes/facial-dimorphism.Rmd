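---
title: "Landmark-based facial dimorphism analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based facial dimorphism analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facedim)
library(dplyr)
```

# The measurement model

The package works on 21 classical anthropometric landmarks (frontotemporale,
exocanthion, endocanthion, nasion, pronasale, subnasale, alare, subalare,
labiale superius/inferius, stomion, cheilion, trichion, glabella, pogonion),
annotated in 3D on a face scan in millimetres. Paired landmarks carry
explicit `_L`/`_R` codes; side is never inferred from coordinates, so the
pipeline is indifferent to head pose. From one landmark set,
`compute_distances()` derives 23 named facial distances (forehead width,
outer canthal width, nasal bridge length, ... lower profile height), each a
straight-line 3D Euclidean distance between its two endpoint landmarks —
not a geodesic along the skin surface. Alar length is the lone composite:
the subalare–pronasale span exists on both sides, so the reported value is
the mean of left and right, which keeps the measure side-agnostic.

Missing landmarks cause the affected distances to be *omitted with a
warning*, never imputed. Imputation would pull group means toward the
template and silently shrink group differences, which is exactly the
quantity downstream analyses estimate.

Facial surface area is computed from a triangulated mesh as the sum of
half cross-product magnitudes per triangle. Degenerate (zero-area)
triangles, common as slivers in real scan meshes, contribute nothing and
raise a warning rather than an error.

# The statistical pipeline

## Sex-dimorphism discovery

`run_study1()` chains three stages:

1. **Relevance ranking.** `mrmr_rank()` orders the 23 distances by
   minimal-redundancy maximal-relevance. Mutual information is estimated
   by a plug-in histogram after equal-frequency discretisation (default 8
   bins). Equal-frequency (quantile) binning makes the estimate invariant
   to monotone rescaling and robust to skew, and leaves no
   density-estimation hyperparameters. The difference criterion
   (relevance minus mean redundancy with the already-selected set, "MID")
   is the default because it is numerically stable when redundancies are
   near zero; the quotient variant ("MIQ") is available behind a flag.
   Ties break by alphabetical feature name so rankings are deterministic.

2. **Subset selection.** `select_optimal_subset()` evaluates nested
   prefixes of the ranking with stratified tenfold cross-validated linear
   discriminant analysis and keeps the prefix with the highest mean
   per-class accuracy (ties to the smaller subset). Exhaustive search over
   all 2^23 subsets is intractable and prefix search over the mRMR order
   is standard practice; this is an interpretation, since no search
   protocol over subset sizes accompanies the published six-feature
   result.

3. **Confirmation.** Pooled two-sample t-tests with the
   variance-explained effect size r² = t²/(t² + df) for each selected
   feature.

## The linear discriminant and the gender score

`fit_lda()` implements the two-class Gaussian/Fisher discriminant
directly: the weight vector solves `S_pooled w = μ_male − μ_female`, and
the threshold is the midpoint of the projected class means shifted by the
log prior ratio. The continuous *gender score* of a face is its signed
distance from the decision hyperplane; positive reads male. Priors default
to equal — the reference cohort is nearly balanced (107/101) and per-class
accuracy reporting presumes no prior advantage for either class. A
singular or ill-conditioned pooled covariance triggers a ridge term
λ = 1e-6·trace/p with a warning: deterministic, and negligible relative to
anthropometric variance scales.

Cross-validation is stratified by class with a seeded shuffle (default
seed 20150415) and reports accuracy from the pooled out-of-fold
predictions. Whether published accuracy figures of this kind are pooled or
fold-averaged is generally ambiguous; both are returned
(`per_class`/`overall` vs `fold_accuracy`).

## Trait-group comparison

`run_study2()` compares high- vs low-trait (AQ) groups within one sex:
pooled t-tests per distance, a facial-area control (a group difference in
overall face size would confound all linear distances), direction calls,
and a discriminant function analysis over the significant distances.

The *direction call* reads the sign of the high-minus-low shift against
the sign of the male-minus-female dimorphism. For males, a significant
shift against the dimorphism direction is `less_sex_typical`
(hypomasculinised) and along it `more_sex_typical`; for females the
reading inverts, since moving toward male-typical values makes a female
face less sex-typical. Non-significant shifts are `null` at α = .05, with
no multiple-testing correction by default — matching the analysis style
the package reproduces, which tests six distances per sex uncorrected.
`stats::p.adjust()` composes naturally with the returned tibbles for users
who want Holm-adjusted calls.

## Discriminant function analysis

`fit_dfa()` computes canonical discriminant weights as the leading
eigenvector of W⁻¹B (within- and between-group scatter), scaled so the
canonical variate has unit pooled within-group variance — the convention
under which standardized coefficients are raw weights times the pooled
within-group SD, `raw_i·√(W_ii/(n−g))`. Eigenvectors are sign-ambiguous,
so the axis is oriented with the high-trait centroid positive, making
coefficient sign patterns comparable across fits. Significance of the
separation uses Wilks' Λ = det(W)/det(W+B) with Bartlett's χ²
approximation, −(n−1−(p+g)/2)·ln Λ on p(g−1) df; the exact F transform
adds nothing at two groups and is not printed in the sources this package
mirrors. Classification uses the Fisher rule with equal priors
(proportional priors behind a flag), and the "cross-validated" percentage
is leave-one-out — the only interpretation consistent with a single
reported percentage and no fold count or seed. For two groups the DFA
direction coincides algebraically with the linear discriminant weight
vector, a property the test suite exploits as an internal oracle.

# The synthetic cohort generator

No raw 3D face scans are publicly deposited for the cohorts this package
is designed around, so `generate_distance_cohort()` emulates them.
Published tables supply only univariate group means and SDs; the generator
therefore draws each group from a multivariate normal with those moments
and a single exchangeable pairwise correlation ρ (default 0.3) —
`Σ_ij = sd_i·sd_j·(ρ + (1−ρ)[i = j])`. An exchangeable structure is the
simplest one that separates univariate effect sizes from multivariate
classification performance. Multivariate normality is consistent with the
pooled t-tests and discriminant models applied downstream. Rows containing
any non-positive value (probability ~1e-4 at the published moments) are
redrawn so cohorts always satisfy the positivity contract; the bias is
negligible at these effect scales. Everything is deterministic given the
spec seed.

`study1_spec()` carries the published male/female moments for the six
dimorphic distances plus *fabricated* sex-invariant moments for the 17
remaining distances. These filler values are flagged synthetic: they exist
only so feature selection faces a realistic 23-feature search space, and
they carry no sex signal. `study2_spec()` carries the published low/high
trait-group moments per sex, including facial area. The trait-group
philtrum means (≈23 mm) are stored verbatim although they are inconsistent
in scale with the sex-comparison philtrum (≈7–8 mm); the row is treated as
suspect and excluded from generator-closure checks.

**What passing tests on synthetic cohorts do and do not show.** The
generator reproduces published first and second moments and a plausible
correlation level, so recovery tests demonstrate that the pipeline detects
effects of the published size at the published (or inflated) sample sizes.
They do not validate the multivariate geometry of real faces: the true
inter-distance correlation matrix is unknown and certainly not
exchangeable, real distances are bounded and mildly skewed, and landmark
annotation error is absent. Published classification accuracies obtained
on the real scans (97.19%/95.04% for sex; 89.7%/88.9% for trait groups)
are therefore *not* reproducible quantities — they depend on the
unavailable raw covariance — and no test asserts them.

One instructive consequence of the exchangeable model: with ρ = 0.3 the
six dimorphic features alone give a theoretical per-class LDA accuracy of
Φ(Δ/2) ≈ 88.9%, while adding the 17 sex-invariant fillers *raises* it to
≈ 95.6%, because the fillers measure the shared latent factor and let the
discriminant subtract it. Accuracy-maximising subset selection on such
cohorts correctly keeps filler features; selecting *only* the six true
features and exceeding 90% per-class accuracy are jointly attainable only
as ρ → 0. This is a property of the simulation model, documented here so
selection results on synthetic cohorts are read correctly.

## Landmark-level generation

`generate_landmark_cohort()` maps sampled distance vectors back to 3D
coordinates by deforming a fabricated, bilaterally symmetric 21-point
template (`face_template()`; no subject coordinates are published, so only
its induced distances matter). Exact constructions exist for the six
dimorphic distances — paired widths set symmetric x-offsets, the
nasion–subnasale–pronasale triangle is solved by sphere–sphere
intersection in the midline plane, philtrum length places labiale
superius along the template direction — plus nose height, the remaining
paired widths, upper facial height, forehead height, mandible height and
lower vermillion height. Distances without an exact construction follow
the template's proportions approximately. Targets violating the triangle
inequality in the nose (e.g. a 0.1 mm nasal bridge with a 60 mm nose
height) raise an infeasibility error naming the offending distances.
Deforming the template to its own measured distances returns the template
exactly, a fixed point the tests assert to 1e-9.

`generate_icosphere()` provides the area oracle for mesh code: a
subdivided icosahedron inscribed in the sphere, whose area approaches
4πr² from below (0.12% low at 4 subdivisions).

# Numerical and reproducibility choices

- Pooled (equal-variance) t throughout, not Welch: the reproduced degrees
  of freedom (206, 56, 52) equal n₁+n₂−2, which identifies the pooled
  form. Two-tailed p-values.
- r² = t²/(t²+df), the unique formula consistent with every published
  t/r² pairing (t = 14.30 on 206 df gives .50).
- The significant-predictor rule for standardized DFA coefficients is
  strict: |coefficient| > .30, so a coefficient of exactly −.30 is not
  flagged.
- All stochastic steps (cohort generation, fold shuffles) take explicit
  integer seeds; fixed seed means byte-identical outputs, which the report
  writer (`write_report()`) relies on by embedding the seed, a config hash
  and the package version in every report.
- Simulation-based checks in the test suite use cohorts of roughly 2,000
  subjects per sex for recovery and 200–500 replicates for calibration —
  sizes at which the asserted properties are stable without making the
  suite slow.

# Known limitations

- Distances are straight-line; no geodesic, curvature or asymmetry
  measures.
- The statement that twelve landmarks were annotated in the trait-group
  study is not enforced: the six dimorphic distances need only ten
  distinct landmarks, and the reader accepts any subset of the 21 codes.
- Facial area is computed over the whole supplied mesh; whether published
  areas used a cropped region is unknown, so mesh cropping is the caller's
  responsibility.
- Only two-group discriminant analysis is provided; no stepwise variable
  entry, quadratic or kernel discriminants.
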