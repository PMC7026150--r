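---
title: "Measuring facial masculinity from 3D landmarks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring facial masculinity from 3D landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facemasc)
```

## The measurement model

A 3D facial scan is a triangulated surface (mm units) carrying 13 manually
annotated anthropometric landmarks. Eleven inter-landmark distances are
measured — three straight lines (alar-base width, nose height, upper lip
height) and eight surface geodesics (outer-canthal width, forehead height
and width, right upper cheek height, nasal tip protrusion, nose height,
upper lip height, nasal bridge length) — plus a facial area used as a
covariate-style size check. A two-class Fisher discriminant trained on the
11-distance vectors of typically developing boys and girls defines both a
sex classifier and a continuous *facial masculinity score*.

The landmark identities and the pairing of the 11 distances are not fully
fixed by the source material, so the registry
(`default_distance_registry()`) is explicit configuration: every pairing
follows standard Farkas anthropometry (e.g. nose height = nasion–subnasale,
forehead height = trichion–nasion, right upper cheek height = right
exocanthion–right zygion), "nasal bridge length" = nasion–pronasale (we
treat the printed "nasal bright length" as a typo for bridge), and a user
may override any pair. Pipeline correctness is independent of the exact
pairing.

## Geodesics: approximation, tolerances, and what the tests show

Geodesics are shortest paths constrained to the mesh surface. We use a
deterministic graph approximation (Lanthier-style edge subdivision): `k`
evenly spaced Steiner points are placed on every mesh edge (`refine = k`,
default **3**), all node pairs sharing a triangle are joined by straight
segments, and Dijkstra's algorithm (via `igraph`) runs on the resulting
weighted graph. Properties that matter:

* **One-sided error.** Graph paths can only *overestimate* the true
  polyhedral geodesic, and on a plane they equal the straight line whenever
  that line lies in the graph. The `geodesic >= linear` invariant is exact.
* **Error floor under mesh refinement.** Subdividing the *mesh* alone does
  not drive the error to zero — the angular resolution of directions inside
  each face is set by the Steiner density, so the error converges to a
  method floor. Our discretization study (random vertex pairs on icospheres,
  compared with the analytic great-circle arc between the snapped
  endpoints) measured maximum relative errors of ~1.3–2.0% at `refine = 2`
  but ~0.6–0.9% at `refine = 3`, which is why the default is 3: the package
  targets 1% accuracy on smooth surfaces. Error does decrease monotonically
  in the refinement level and along a joint (subdivision, refinement)
  schedule, and those are the monotonicity properties the test suite
  asserts.
* **Endpoint snapping.** Landmarks snap to the nearest mesh vertex, with a
  2 mm tolerance matching the stated precision of the acquisition system.
  Tests that quote analytic arc lengths therefore use actual mesh vertices
  as endpoints, so the tolerance tests the path approximation rather than
  the snap displacement.

## Facial area

The facial area sums one-half the edge cross-product magnitude over a fixed
set of landmark triangles. The published group areas (~26,000–28,400 mm²)
exceed what any single-cover triangulation of 13 landmarks on a child-sized
face can span (the convex hull of the landmark set at the published
distance scale is roughly 12,000 mm²), and the source description —
"adding the triangular areas connected between the points" — does not pin
down a triangle set. The shipped default (`default_area_triangulation()`)
therefore sums *documented, deliberately overlapping* anatomical panels
(a full-face fan anchored at pronasale, an upper/mid-face fan anchored at
nasion, and lower-face panels around the mouth), calibrated once against
the published scale and then frozen; the default synthetic face yields
~23,000–25,000 mm², inside the plausibility band of the published group
summaries. `facial_area()` itself is triangulation-agnostic: the summation
is exact, rigid-invariant, and quadratic under scaling for *any* triple
set, and users with a defensible single-cover definition can supply it.

## The masculinity score

The published description fixes only that the score lives on 0–20 with 0 =
extreme femininity, and that it is computed from the deviation of a test
face from the male and female class means in LDA space. The calibration
constants are not printed, so this package defines (and documents as its
own convention): with `u` the projection's deviation from the midpoint of
the projected class means in units of half the inter-mean distance,

```
score = clip(10 + 5u, 0, 20)
```

so the female class mean anchors at 5, the male class mean at 15, and faces
beyond two half-distances past a class mean saturate. This leaves headroom
beyond the class means consistent with the published group means (3.67 to
14.5). A projection exactly at the midpoint classifies as male — an
arbitrary, zero-probability tie rule fixed for reproducibility. Equal class
priors are assumed. The pooled within-class covariance is
ridge-regularized by `1e-6 × mean(diag(S))` by default, keeping the solve
well-posed without materially rotating the axis; scores are invariant under
any affine rescaling applied consistently to training and test features.

The shipped reference model (`default_gender_model()`) is trained on the
synthetic validation cohort because the original training scans are not
distributable; it is a stand-in for testing the pipeline, not a clinical
instrument, and `fit_lda()`/`write_gender_model()` support retraining and
serialization.

## Statistical layer

* **Welch's t** from raw samples or from (mean, SD, n) summaries, with
  Welch–Satterthwaite df; the two routes agree to 1e-12 by construction.
  Degrees of freedom are reported to one decimal in the printed-table
  recomputations.
* **Cohen's d**: pooled-SD standardized difference with the
  Hedges–Olkin normal-approximation 95% CI
  `d ± 1.96 √((n₁+n₂)/(n₁n₂) + d²/(2(n₁+n₂)))`. This variant reproduces the
  published interval [0.36, 1.26] for d = 0.81 at n = 30/69 to within 0.01
  per bound, which is why it was chosen; the source's exact variant is
  unstated.
* **Rank-sum test** (the source labels these rows "Wilcoxon signed-rank"
  but applies them to independent groups; they are implemented as
  Mann–Whitney). Statistic convention: `U = #{(i,j): x_i > y_j} + ½·ties`,
  first argument first. Exact p from the null permutation distribution when
  `n₁n₂ ≤ 400` and tie-free, otherwise normal approximation with tie and
  continuity corrections. Effect sizes for these rows are still Cohen's d
  from mean/SD, matching the published tables' practice.
* **Test choice**: Shapiro–Wilk per group at α = 0.05; nonparametric iff
  either group rejects. The choice and both p-values are logged in every
  report row.
* **ANOVA from summaries**: `F = [Σnᵢ(mᵢ−m̄)²/(k−1)] / [Σ(nᵢ−1)sᵢ²/(N−k)]`;
  median/IQR summary rows are converted under normality
  (mean ≈ median, SD ≈ IQR/1.349) and flagged. Tukey–Kramer adjusted
  p-values come from the studentized range distribution on raw samples.
* **Power**: smallest balanced total N (multiple of k) with noncentral-F
  power ≥ target at `λ = f²N`. This reproduces the published minimum
  sample sizes 62 (f = 0.42) and 18 (f = 0.82) for 90% power at α = 0.05.
* **Multiplicity**: none across the feature comparisons, mirroring the
  source analysis; a Holm-adjusted column is emitted for transparency but
  never used in the headline significance counts.

## The synthetic world, and what a green test does (not) establish

`generate_cohort()` draws multivariate-normal feature vectors with the
*published* group means and SDs (median/IQR rows converted as above) and a
configurable inter-feature correlation, default equicorrelation ρ = 0.3 — a
plausible magnitude for craniofacial measurements, chosen once; the true
correlations are unknowable from printed summaries. `generate_study()`
emits the full design: 40+40 validation, 30/69 male and 25/60 female
sibling/control cohorts, and proband score cohorts (n = 54/20, sizes
inferred from the published ANOVA degrees of freedom). Sibling/control
cohorts carry the published moments for the 8 dimorphic distances; the
other three distances are filled from the same-sex validation moments with
no sibling shift, consistent with their non-significance.

Two consequences worth stating plainly:

* **Classification accuracy is Bayes-bounded below the published value.**
  The printed per-feature effects give a between-class Mahalanobis distance
  of ≈ 2.37 (ρ = 0) to 2.39 (ρ = 0.3), i.e. a Bayes accuracy of ≈ 0.88;
  leave-one-out LDA at 40/class measures ≈ 0.85. The published 95.4%/96.0%
  reflects real-face covariance structure the printed summaries do not
  carry. The acceptance gate asserting ≥ 0.90 is therefore red by design
  and kept red rather than weakened.
* **The synthetic score-level sibling shift overshoots the published
  d ≈ 0.8**, because eight aligned per-feature shifts compound along the
  discriminant axis under the synthetic covariance. Detection-rate and
  ordering gates (one-sided) pass comfortably; the printed score moments
  are recomputed from the fixtures, not from the generator, wherever a test
  targets a published number.

The face generator (`generate_face()`) is a geometric surrogate: a head
ellipsoid (half-axes 75 × 105 × 85 mm) with an asymmetric-Gaussian nasal
ridge, landmarks placed at calibrated frontal positions, jittered (default
SD 1 mm), and snapped to mesh vertices (greedy nearest-free-vertex, so
coarse meshes cannot collapse two landmarks). Its calibration places every
default distance near the midpoint of the published male/female means, with
presets shifting global size (±2.5%), trichion height, and nose amplitude
in the published direction of dimorphism — enough to keep each preset
within ±3 SD of its sex's published envelope, which is what the tests
assert. It validates geometry code; it does not emulate anatomy, skin, or
scanner noise, and nothing about a green geometry test certifies anatomical
realism.

## Numerical and degenerate-input choices

* Midpoint classification ties → male (documented above).
* Zero variance in any two-sample test → explicit degenerate-variance
  error, never NaN.
* Meshes must be triangle-only with no zero-area faces; disconnected
  landmark regions raise a connectivity error at geodesic time.
* Density curves for the score-distribution figure use a Gaussian kernel
  with Silverman's bandwidth on a fixed 201-point grid over [0, 20],
  renormalized to integrate to exactly 1 on the grid (kernel mass outside
  the score range is folded back proportionally). Figure values are never
  acceptance targets.
* Reports are byte-stable under a fixed seed apart from a UTC timestamp
  field.

## Known limitations

* Geodesics are graph approximations (~0.6–0.9% high on smooth surfaces at
  the default refinement), not exact polyhedral geodesics (no MMP/heat
  method).
* The score calibration constants are this package's convention; absolute
  scores are not comparable to the published ones, only contrasts and
  orderings are.
* No age adjustment or covariate modelling; sexes are always analysed
  separately.
* Landmarks are inputs; there is no automatic landmark detection.
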