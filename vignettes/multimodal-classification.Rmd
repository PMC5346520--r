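---
title: "Multimodal single-subject classification with WAVE fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal single-subject classification with WAVE fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waveclass)
```

`waveclass` implements a single-subject diagnostic classification pipeline
for a generalized anxiety disorder (GAD) / major depression (MD) / healthy
control (HC) cohort: linear support-vector-machine classification of four
data modalities under leave-one-out cross-validation (LOOCV), permutation
significance, and multimodal fusion by a weight-adjusted voting ensemble
(WAVE) inside a nested LOOCV. This vignette is the package's account of the
model, its assumptions, the tunable parameters, and the design decisions
taken where the procedure was genuinely open.

## The two classification problems

* **Case-classification**: GAD and MD subjects (the positive,
  "sensitivity" class) against HC. All subjects enter.
* **Disorder-classification**: GAD subjects — irrespective of comorbid MD —
  (positive class) against MD-only subjects. HC are excluded.

Both are binary, evaluated by sensitivity, specificity and balanced
accuracy $(\mathrm{sens}+\mathrm{spec})/2$, which is robust to the group
imbalance (33 vs 24, and 19 vs 14, in the reference design).

## Per-modality classification

**Model.** A linear soft-margin SVM with fixed cost $C = 1$. No
hyperparameter search is performed: with $n \le 57$ subjects any tuning
would consume data the cross-validation cannot spare, and the linear primal
weights are themselves the object of interest (weight maps). The cost is
configurable (`cost` argument) for sensitivity analyses.

**Scaling.** Features are mean-centered and scaled to unit standard
deviation per column. The scaler is estimated on the training rows of each
fold only and applied frozen to the held-out subject — estimating it on the
full sample would leak the held-out subject's values into training.
Because some published pipelines normalize before cross-validating, a
`scaling_fit = "all"` switch reproduces that variant; the default is
`"train"`. Constant columns are centered and passed through with a
zero-scale guard (scale set to 1).

**Ties.** A held-out decision value of exactly zero predicts the positive
class. In a diagnostic setting the cost of missing a case exceeds the cost
of a false alarm, and the reference analyses show the same
sensitivity-over-specificity preference.

**Permutation test.** The whole LOOCV is re-run under random unstratified
shuffles of the label vector; the p-value is the add-one estimator
$p = (\#\{\mathrm{null} \ge \mathrm{obs}\} + 1)/(N+1)$, which can never
return 0 and is exact under exchangeability. 5000 permutations match the
reference analysis; the test suite uses 199 for runtime. Whether the
original analysis counted `>` or `>=` is not stated; `>=` is the
conservative choice. Note that an unstratified shuffle occasionally
reproduces the original labelling (or its mirror image), so even a perfect
classifier can receive $p > 1/(N+1)$.

**Weight maps.** Per-fold primal weight vectors
$w = \sum_i \alpha_i y_i x_i$ are averaged across folds *signed*; absolute
values are taken only at the region-summary stage, where each region's
score is the mean of $|w_j|$ over its features and percentages are the
region scores normalized to 100. Ranking ties break by region name for
determinism; percentages are reported to two decimals.

## Cortisol release

Total release over the sampling window is the area under the
log-transformed concentration curve with respect to the ground
(trapezoidal rule over the actual sampling times). The reference
descriptives (log-AUC means of roughly 160–200 over a 100-minute window
with concentrations in nmol/L) are consistent with the natural log, not
log10 (which would give values an order of magnitude smaller), so natural
log is the default; `log_base` is configurable and flagged. Profiles with
fewer than six samples, missing values, or nonpositive concentrations are
excluded, and — because ensemble fusion needs every modality for every
subject — excluded subjects are dropped from *all* modalities before
fusion (`multimodal_features()` handles this).

## Imaging features

Voxelwise GM/WM volume maps are restricted to an **intersection mask**:
voxels with strictly positive values in every subject (threshold
configurable, since VBM practice sometimes uses small positive cutoffs).
GM features are further restricted to 30 region-of-interest parcels
(frontal and orbitofrontal gyri, anterior cingulate, amygdala,
hippocampus, putamen, nucleus caudate, thalamus — left and right
separately); WM features to a WM compartment mask; a `whole_brain` policy
drops the GM ROI restriction. Intersection and ROI masking commute, so the
order is immaterial. Analysis is index-based on one shared grid; NIfTI
affines are respected for I/O only.

## WAVE fusion under nested LOOCV

From the binary performance matrix $X$ ($n$ subjects × $k$ classifiers,
$X_{ij} = 1$ when classifier $j$'s held-out prediction for subject $i$ was
correct), WAVE iterates

$$q \propto (1 - X)\,p, \qquad p \propto X^\top q,$$

with $L_1$ normalization from uniform starts until the maximum absolute
change falls below `tol` (default 1e-10, cap 1000 iterations — typical
convergence is well under 100). Subjects missed by currently-good
classifiers are "difficult"; classifiers correct on difficult subjects
gain weight. All-correct or all-wrong matrices return uniform weights with
a `degenerate` flag. The fixed point lives in the simplex at every
iteration and is equivariant under subject and classifier reordering; an
independent brute-force iteration backs the implementation in the tests to
1e-8.

Fusion must not let the test subject influence its own ensemble, so the
scheme is nested: for each outer held-out subject, the inner LOOCV on the
remaining $n-1$ subjects produces $X$ and $p$; the $k$ classifiers are
then refit on all $n-1$ and vote $\pm 1$; the fused prediction is
$\operatorname{sign}(\sum_j p_j v_j)$ with ties to the positive class.
Whether the inner scaling should be refit inside every inner split cannot
be determined from the reference description; both variants are supported
through `scaling_fit`, defaulting to the leakage-free `"train"`.

**Ensemble permutation test.** The reference scheme fixes the fused
predictions and per-fold weights and rescores them against permuted
labels, counting permutations that *strictly* beat the observed balanced
accuracy and dividing by the number of permutations. This estimator can
return exactly 0 (a documented caveat) and differs from the add-one
estimator by at most $1/N$. Because the description is ambiguous, a
`type = "full"` variant re-runs the entire nested ensemble per permutation
as a sensitivity analysis.

**Weight comparisons.** The reference analysis reports significance of
weight differences without naming the test; `compare_classifier_weights()`
uses paired t-tests across outer folds (flagged as a judgment call).
Zero-variance pairs are flagged: a constant nonzero difference is
deterministic separation ($p = 0$), a zero difference admits no test.

## The synthetic cohort generator

No public data exist for this design (clinical MRI and hormone data were
never deposited), so the generator is a first-class module that emits
cohorts with the statistical structure the analysis assumes:

* **Group structure**: 24 HC, 19 GAD (12 with comorbid MD), 14 MD.
  Demographic category counts (sex, handedness, education, smoking) are
  realized *exactly*, not sampled, so the descriptive chi-square statistics
  are reproducible; one HC subject has missing smoking status, matching
  the reference table's 22-of-23 denominator.
* **Questionnaires**: truncated normals (clipped to instrument ranges,
  rounded to integer sum scores) at the reference per-group means/SDs —
  e.g. PSWQ 36.0 (10.0) in HC vs 62.0 (6.2) in GAD.
* **Cortisol**: each profile is $\exp(a + s)$ on the six sampling times,
  where $s$ is a zero-area shape wiggle and $a$ is set so the subject's
  log-AUC equals a draw from the configured group normal — calibration is
  exact by construction. The exact sampling minutes are not recorded in
  the reference description beyond spanning 100 minutes; the default grid
  0, 10, 35, 55, 75, 100 is configurable. One subject (configurable)
  receives an incomplete profile.
* **Images**: smooth nonnegative fields on a 40 × 48 × 40 grid of 3 mm
  voxels. A box-parcel atlas places the 30 ROI regions plus a WM
  compartment; voxels inside the brain envelope but outside parcels are
  unlabelled GM, so whole-brain selection strictly contains ROI selection.
  Group effects are multiplicative regional volume shifts; the default
  raises frontal GM by 5% in GAD and lowers it by 5% in MD, the direction
  suggested by the morphometry literature on the two disorders (magnitudes
  are configuration, not published values). Per-subject global scaling
  (SD 0.05) emulates brain-size variation, and voxel noise is a Gaussian
  random field smoothed with an 8-mm FWHM kernel and rescaled to marginal
  SD `noise_sd` (default 0.05 against a GM baseline of 0.5). Parcel box
  sizes (12–64 voxels) loosely mirror real parcel volumes while keeping
  GM/WM feature counts near 1000/720, which holds a full nested-LOOCV
  ensemble run to a few seconds.

What the generator does **not** emulate: MRI physics and preprocessing
(segmentation, DARTEL registration, modulation — the maps are born
"preprocessed"), circadian cortisol dynamics or awakening responses,
correlations between questionnaires and biology within subject, and
site/scanner effects. Passing tests on synthetic cohorts therefore
demonstrate the *statistical machinery* — calibration, leakage-freedom,
fixed-point correctness, type-I error control — not clinical
generalization.

Three configurations are exported: `cohort_config()` (reference
calibration), `null_cohort_config()` (no group differences anywhere, for
calibration tests) and `strong_effect_config()` (a widened GAD-low/MD-high
cortisol gap and ±8% frontal GM shifts). Under the strong-effect
conditions the expected qualitative pattern — clinical scores dominate
case-classification while cortisol and GM dominate
disorder-classification — emerges in the large majority of seeds.

## Numerical choices and degenerate inputs

* WAVE: uniform initialization, `tol = 1e-10`, max 1000 iterations;
  normalization exact to 1e-12.
* Scaling: SDs below 1e-12 are treated as constant columns (scale 1).
* Single-class training folds, empty voxel selections, subjects missing
  from a modality, non-binary performance matrices and inconsistent
  configurations (e.g. more comorbid than GAD subjects) raise classed
  errors rather than propagating nonsense.
* All randomness flows through explicit seeds; a cohort is a pure function
  of its configuration.

## A note on chance-level behaviour

Leave-one-out accuracy is *pessimistically* biased under the null: the
held-out subject's removal shifts the training class means away from it,
so null-data LOOCV balanced accuracy sits below 50% ("anti-learning"),
severely so for single-feature classifiers such as cortisol (empirically
≈25–45% on null cohorts, fused ≈30–45%). This is a property of the
estimator, not a bug, and it does not invalidate inference: the
permutation null distribution is built with the same biased procedure, and
the type-I error of the permutation test is calibrated (verified over 100
null cohorts in the test suite). The practical consequence is that raw
LOOCV accuracies near 50% should be read against their permutation p-value
rather than against the nominal chance level.

## Problem sizes used in validation

The test suite scales simulations to keep iteration tight: permutation
calibration uses 100 null cohorts of 16 subjects at 199 permutations
(permutation exactness holds at any sample size, so a compact cohort loses
nothing); the
modality-pattern check uses 20 full-size (57-subject, default-grid)
effect-loaded cohorts; ensemble properties use 12–20-subject toy problems
built in code. `scripts/acceptance.R` runs the full 57-subject pipeline
for both problems at 199 permutations.

## Known limitations

* The WAVE fixed point follows the verbal description of the mutually
  reinforcing weight pair; the originally published formulation has an
  eigen-solution shortcut that is admissible here only if it matches the
  iteration (the tests pin the iteration).
* The disorder problem with 19 + 14 subjects yields noisy LOOCV estimates;
  confidence in any single balanced accuracy is low, which is precisely
  why permutation tests accompany every result.
* Synthetic images are box-parcel caricatures; regional weight rankings on
  synthetic data validate bookkeeping (provenance, normalization), not
  anatomy.
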