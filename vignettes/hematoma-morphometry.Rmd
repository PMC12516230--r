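---
title: "Quantitative hematoma morphometry and expansion-risk modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative hematoma morphometry and expansion-risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ichmorph)
```

## The problem

Hematoma expansion (HE) — growth of an intracerebral hemorrhage between the
baseline CT and a follow-up scan at 24–48 h — is a major driver of early
neurological deterioration, and identifying patients likely to expand is a
long-standing goal of acute stroke imaging. The classical predictors are
qualitative: the CTA spot sign and a family of non-contrast CT signs
(hypodensities, blend, black hole, island, satellite, heterogeneous density,
irregular shape). These are read by eye and suffer from inter-reader
subjectivity. `ichmorph` implements a quantitative alternative: two
continuous descriptors computed directly from the segmented hematoma —

* **SRI** (surface regularity index): $\mathrm{SRI} =
  100 \cdot 6\sqrt{\pi}\, V / S^{3/2}$, sphericity on a 0–100 scale. A
  perfect sphere scores 100; by the isoperimetric inequality every other
  shape scores less. Irregular, multilobulated hematomas — the kind that
  tend to expand — score low. The index is dimensionless and invariant
  under uniform rescaling, so it compares hematomas of different sizes.
* **DCV** (density coefficient of variation): $\mathrm{DCV} = 100 \cdot
  \mathrm{SD}/\mathrm{Mean}$ of the Hounsfield values inside the mask.
  Heterogeneous density — blood of different ages from staggered bleeding
  — raises the DCV.

and the full model-construction and comparison machinery around them:
LASSO-based variable selection, three nested logistic models, nomograms,
and discrimination / reclassification / calibration / decision-curve
evaluation.

HE itself is classified by the standard strict rule: an increase of
**more than 6 mL** absolute or **more than 33 %** relative volume between
baseline and follow-up (`classify_expansion()`; growth of exactly 6 mL or
exactly 33 % does not qualify).

## Morphometry

### Volume

`compute_volume()` counts foreground voxels and multiplies by the voxel
volume — the 3D equivalent of adding up the segmented pixels of every
slice. It is exact with respect to the segmentation and is tested to
machine precision against a direct count.

### Surface area: the staircase problem

The segmentation is a binary grid, so its boundary is a staircase. We
extract the level-0.5 isosurface as a triangle mesh with no smoothing or
decimation (`surface_mesh()`), via marching tetrahedra on a conforming
Kuhn decomposition of an exactly twice-refined trilinear grid — the
chorded trilinear isosurface, equivalent in accuracy to classic marching
cubes but without the 256-entry case table. Masks touching the grid edge
are padded by a background margin so the surface closes; the closure is
tested by checking that the oriented facet areas of the mesh cancel.

The plain sum of facet areas (`method = "raw"`) measures the staircase
itself, and the staircase is *longer* than the smooth surface it
approximates: for a digital sphere the raw mesh area overestimates
$4\pi r^2$ by about 9 % regardless of resolution, because facet
orientations are quantised. Pushed through the SRI formula
($\mathrm{SRI} \propto S^{-3/2}$) that bias would depress a sphere's SRI
to ≈ 88 and contaminate every comparison between shapes.

The default estimator (`method = "corrected"`) therefore keeps every
vertex where the extraction put it and corrects the *area integral*
instead. Each facet's area $a_i$ is weighted by the projection
$|\hat n(x_i) \cdot \hat t_i|$ of its facet normal $\hat t_i$ onto a
smoothly estimated surface normal $\hat n$ (the gradient of the
Gaussian-smoothed indicator, bandwidth $\sigma$ = 1.5 voxels). For a
planar patch of any orientation this weighted sum equals the true area
exactly — the staircase's vector area equals the plane's vector area —
so the orientation bias vanishes wherever the surface is locally flat at
the voxel scale. Near genuinely sharp structure (edges and corners of an
axis-aligned box, say) no coherent smooth normal exists and the
projection weight would wrongly shave area off; an orientation-coherence
factor $c = \|\langle \nabla f \rangle\| / \langle \|\nabla f\| \rangle
\in [0,1]$, raised to the power 8, blends the weight back to 1 there:

$$ S = \sum_i a_i \left[ 1 + c_i^{8}\,(|\hat n_i \cdot \hat t_i| - 1)
\right]. $$

The exponent 8 makes the blend essentially binary: coherent smooth
surface ($c \approx 1$) is fully corrected, incoherent edge
neighbourhoods ($c \lesssim 0.9$) are left at their raw staircase area,
which is already accurate for axis-aligned structure. With this
estimator, at 0.5 mm spacing: a digital sphere's area is recovered to
within ~0.5 % (SRI ≈ 99.4), a 20×10×10 mm axis-aligned box to within
~4 %, a 30°-tilted box to within ~1 %, and irregular star-shaped
phantoms to within ~1 % of an analytic quadrature reference. The sphere's
SRI error also shrinks monotonically as the spacing is refined through
2 → 1 → 0.5 mm.

### Density statistics

`compute_dcv()` uses the sample SD (divisor $n-1$; configurable to the
population divisor — the difference is negligible at hematoma voxel
counts). A non-positive mean HU inside the mask makes the ratio
meaningless and is a flagged error, never a silent value. The mask is
measured as given — a multilobar hematoma counts as one object — with an
optional `largest_component` filter for segmentations known to contain
stray islands.

### Geometry conventions

Grids are treated as axis-aligned: only the header's voxel spacing is
interpreted, never the affine rotation, because every quantity here
(volume, area, SRI, DCV) is rotation-invariant. Anisotropic spacing is
fully supported; the phantom default (0.45 × 0.45 × 1 mm) mirrors a
thin-slice clinical CT. Loading applies no HU clipping inside the mask.

## The phantom generator

`generate_phantom()` builds star-shaped surfaces $r(\theta,\varphi) =
R\,(1 + A\,f(\theta,\varphi))$ with $f$ a seed-drawn random field on a
low-order real spherical-harmonic basis (degree ≤ `perturbation_degree`),
normalised to peak amplitude 1 so the radius stays positive for $A < 1$.
This family was chosen because the continuous surface has closed-form
spherical-coordinate quadratures: `reference_geometry()` integrates
$V = \oint \tfrac{r^3}{3}\sin\theta \,d\theta\,d\varphi$ and
$S = \oint r\sqrt{(r^2 + r_\theta^2)\sin^2\theta + r_\varphi^2}
\,d\theta\,d\varphi$ on a 512 × 1024 midpoint grid (derivatives by
central differences continued smoothly across the poles; doubling the
grid moves the results by under 0.1 %), giving an independent oracle for
the voxel-based measurements.

Inside the mask the attenuation is `base_hu` (default 60 HU, the acute
hematoma range) plus i.i.d. Gaussian noise and optional hypodense
spherical inclusions (emulating the substrate of the hypodensity signs);
the background is 30 HU, roughly brain parenchyma. Larger perturbation
amplitude lowers the measured SRI; more noise or more inclusions raises
the measured DCV — both monotonicities are tested.

What the phantoms do *not* emulate: CT physics (beam hardening, partial
volume at the rim), skull and ventricle anatomy, segmentation error.
Passing tests therefore demonstrate that the *measurement and modelling
machinery* is correct, not that the pipeline is robust to real
segmentation noise.

## The cohort generator

`generate_cohort()` draws the HE label first (default prevalence 19.2 %)
and every other column conditionally on it:

* the eight binary signs from label-conditional prevalences (spot
  20.0 %/5.1 %, hypodensities 62.9 %/42.5 %, satellite 32.9 %/21.1 %,
  heterogeneous 25.7 %/11.2 %, irregular 32.9 %/19.4 %; the three signs
  without published pairs — blend, black hole, island — default to
  15 %/10 %);
* SRI from a log-normal truncated to (0, 100], with the *truncated*
  median solved numerically to sit exactly at 56.9 (HE) / 75.9 (no HE);
  DCV from a normal truncated at 0, medians 13.5 %/11.9 %;
* leukocyte count and total protein from label-conditional normals.
  Their published distributions are not available, so the defaults
  (leukocytes 10.5 ± 3.0 vs 8.6 ± 2.5 ×10⁹/L; protein 66 ± 6 vs
  69.5 ± 6 g/L) are clinically plausible shifts in the direction that
  makes them selectable — chosen once and documented here, not fitted to
  anything;
* baseline volume log-normal (median 23.8 mL) and a follow-up volume
  *constructed* so that `classify_expansion()` reproduces the label for
  every record — an invariant the tests assert row by row.

Signs are conditionally independent given the outcome (no joint structure
is published). Every column draws from its own named random stream
derived from the single seed, so adding a column never perturbs existing
ones. `generate_risk_cohort()` is the lightweight variant for
parameter-recovery and null studies: (SRI, DCV) marginals, optional
N(0,1) noise covariates, and a label drawn from an explicit logistic
model whose coefficients are attached as ground truth.
`generate_phantom_cohort()` closes the loop end-to-end: per-patient
phantoms are generated, *measured* through the morphometry pipeline, and
the label is drawn from a logistic model on the measured values.

## Model construction

`build_model_suite()` reproduces the three-model design:

1. **Encoding** (`encode_features()`): categoricals one-hot with the
   reference level dropped; binary signs kept as plain 0/1 indicators
   (not standardised); continuous covariates standardised with the
   sample SD. Transforming new data always reuses the training
   statistics; an unseen level is an error naming the level.
2. **Selection**: an L1-penalised logistic path (`lasso_logistic_path()`,
   glmnet backend; 100 log-spaced penalties over four decades down from
   the analytic $\lambda_{\max}$), tuned by outcome-stratified 5-fold
   cross-validation minimising mean out-of-fold binomial deviance
   (`select_lambda_cv()`; the minimum-error criterion, not the
   one-standard-error rule). `select_top_k()` keeps the 7 variables with
   the largest absolute standardised coefficients at $\lambda_{opt}$ —
   7 because a ~70-event derivation cohort supports 7 predictors under
   the 10 events-per-variable budget. One-hot levels aggregate to their
   source variable (scored by the largest |coefficient| among levels) so
   a categorical counts once; exact ties break lexicographically; fewer
   than 7 non-zero coefficients returns all of them with a warning.
3. **Models**: Model 1 = the selected seven, refitted by unpenalised
   logistic regression on the raw scale; Model 2 = Model 1 + SRI + DCV;
   Model 3 = Model 1's clinical (non-sign) variables + SRI + DCV. The
   CTA spot sign is treated as an imaging sign and dropped from Model 3
   along with the NCCT signs — the quantitative markers are meant to
   *replace* image reading, and a model that still required CTA would
   not simplify acquisition.

Perfect separation in the final fits raises an error rather than
returning a silently regularised fit, because diverging coefficients
would make the nomogram point scales meaningless. `nomogram_table()`
maps each variable's observed range onto 0–100 points (the largest
|coefficient| × range spans exactly 0–100; points are affine in the
variable's contribution and direction-aware), and the total-points →
risk lookup is exactly consistent with `predict_risk()` — tested to
1e-6.

## Evaluation

All statistics are implemented from first principles and tested against
brute-force enumeration oracles:

* `auroc()`: midrank Mann–Whitney estimator, ties counted ½; exact
  against pair enumeration for every tested instance.
* `delong_test()`: placement-value (structural component) covariances;
  the variance matches direct enumeration to 1e-12; identical scores
  give p = 1 by convention, logged.
* `continuous_nri()` / `idi()`: strict up/down counting and mean-risk
  separation; antisymmetric under swapping old and new.
* `bootstrap_ci()`: percentile intervals from patient-level resampling
  (the headline analyses use B = 5000); single-class resamples are
  redrawn and counted; the bootstrap stream is seed-deterministic.
  Percentile rather than BCa, matching the plain resampling description;
  NRI/IDI intervals hold the models fixed across resamples by default,
  with a `refit` option.
* `calibration_curve()`: equal-count decile bins (collapsed with a
  message when predictions tie); no smoothing by default.
* `decision_curve()`: $NB(p_t) = TP/n - FP/n \cdot p_t/(1-p_t)$ on a
  0.01–0.99 grid; the clinically quoted 0.15–0.5 window is a reporting
  overlay, not a computational constraint.
* `crossval_evaluate()`: outcome-stratified folds; the *entire* recipe —
  encoding, selection, fitting — is re-run inside each training fold
  (`selection_recipe()`), and out-of-fold predictions are pooled.

## Numerical choices and degenerate inputs

* Surface estimator bandwidth $\sigma$ = 1.5 voxels and coherence power
  8, fixed once from the planar-exactness / edge-preservation trade-off
  described above.
* Mask binarisation threshold 0.5 everywhere; binarisation is
  idempotent.
* Read/write round trips are bit-exact (volumes stored as doubles,
  masks as uint8); mask/volume alignment requires identical grids and
  header spacing within 1e-3 mm.
* Empty masks, non-positive mean HU, single-class outcomes, zero-SD
  covariates, unseen factor levels, non-positive baseline volumes and
  out-of-range DCA thresholds are all explicit errors, not NA
  propagation.
* Percentages in cohort summaries round half-up at one decimal,
  matching conventional clinical reporting (R's own `round()` is
  half-even).

## Problem sizes used in the tests

The test suite and acceptance script exercise: digital spheres up to
r = 15 mm at 0.5 mm spacing (~113k foreground voxels), 20 seeded
irregular phantoms against the quadrature oracle, cohorts of n = 364
(the study scale) for the end-to-end suite, n = 2000 × 50 replicates for
coefficient-coverage checks, and n = 100 000 for generator calibration
checks. Bootstrap sizes are reduced (B = 200–2000) outside the headline
B = 5000 setting. These sizes were chosen so the full suite completes in
a couple of minutes while keeping every Monte-Carlo band at least three
standard errors wide.

## Known limitations

* The surface correction assumes the object is smooth at the voxel
  scale except on a sparse edge set; a surface that is *everywhere* as
  sharp as a voxel (fractal-like segmentation noise) would be measured
  close to its raw staircase area.
* The cohort generator's conditional-independence structure cannot
  reproduce correlations among signs; recovered model coefficients on
  synthetic cohorts should be read as generator recovery, not clinical
  effect sizes.
* DeLong p-values are asymptotic normal; with very few events (< ~10)
  the bootstrap intervals are the more trustworthy summary.
* SRI depends on the surface-area convention; values from pipelines
  that smooth their meshes are systematically higher and should not be
  mixed with values from this package's raw-mesh convention without
  re-deriving cut-offs.
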