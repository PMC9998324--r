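---
title: "Methods: synthetic cine CMR volumetry and Task Force Criteria scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cine CMR volumetry and Task Force Criteria scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arvcmr)
```

## The problem this package addresses

Arrhythmogenic right ventricular cardiomyopathy (ARVC) is diagnosed with a
point-based system, the 2010 Task Force Criteria (TFC): six categories each
contribute 0 points (no criterion), 1 (minor) or 2 (major), and a definite
diagnosis requires at least 4 points in total. One category is assessed on
cardiovascular magnetic resonance (CMR): it requires a regional RV
wall-motion abnormality (RWMA) *plus* either a reduced RV ejection fraction
(RVEF) or a dilated, body-surface-area-indexed RV end-diastolic volume
(RVEDVI), with sex-specific volume cutoffs:

* **major**: RWMA and (RVEF ≤ 40% or RVEDVI ≥ 110 ml/m² in men /
  ≥ 100 ml/m² in women);
* **minor**: RWMA and (40 < RVEF ≤ 45% or RVEDVI in [100, 110) ml/m² in
  men / [90, 100) ml/m² in women).

Deep-learning segmentation of short-axis cine CMR can automate the
volumetry behind RVEF and RVEDVI, but automatic contours are least reliable
in the most basal slice, where the ventricular–atrial transition is
ambiguous. A practical middle ground is *simulated expert correction*:
replace the automatic segmentation of the most basal slice with the manual
reference and recompute everything ("automatic⁻ᵇᵃˢᵃˡ"). This package
implements that entire analysis chain on synthetic data, so every stage —
phase selection, volumetry, correction, TFC scoring, agreement statistics —
is testable end to end without any clinical images.

## The synthetic cohort generator

`generate_cohort()` draws subjects from three groups — controls, at-risk
family members, and ARVC patients — with the composition of a 157-subject
evaluation cohort (54/66/37) as the default proportions. Group sizes are
apportioned by deterministic largest remainder by default (multinomial
sampling is available), so the canonical cohort reproduces exactly.

Each subject carries sex, age, body surface area, an RWMA flag, a non-CMR
TFC point total, and ground-truth volumetry: per-structure EDV/ESV derived
from group-level distributions of indexed volumes and ejection fractions.
The distributional defaults are plausible clinical values, *not* values
extracted from any specific dataset (per-group distributions are published
only as boxplots and supplementary summaries): controls around
RVEDVI 75 ± 10 ml/m² and RVEF 58 ± 6%, at-risk subjects mildly dilated,
ARVC patients at RVEDVI 112 ± 22 ml/m² and RVEF 40 ± 8%, with an 8 ml/m²
downward shift of indexed volumes in women. Draws are truncated at
±2.5 SD to keep phantoms physically realizable. The RWMA probabilities
(0.05 / 0.20 / 0.90) were chosen once so that roughly 84% of ARVC subjects
and about 3% of at-risk subjects meet a minor-or-major CMR criterion —
calibration targets, not guarantees.

### Volume curves and phantom geometry

Ventricular volume over the cycle is a cosine-based, strictly unimodal
curve (`volume_profile()`): end-diastole at the first phase (maximum) by
generator convention, end-systole at a configurable fraction of the cycle
(default 0.40 ± 0.02), half-cosine limbs in between. Phase counts are drawn
from 25–40 per subject; in-plane spacing from 1.11–1.45 mm and slice
thickness from 7–10 mm, matching typical short-axis acquisitions.

`rasterize_phantom()` renders the LV as a disc and the RV as a crescent
partially wrapping it (a 220° wedge opening away from the LV), both
tapering linearly in cross-sectional area from base to apex. Per slice the
generator takes exactly the target number of voxels in a nearest-first
ordering, so the voxel-counted volume matches the curve to within half a
voxel per slice — comfortably inside the 5% fidelity bound the test suite
enforces. One empty slice is kept below the apex and above the base so
out-of-extent segmentation errors have somewhere to live. The geometry is
deliberately crude: no trabeculation, papillary muscles, outflow tract, or
breathing artefacts. It exercises the downstream operators; it does not
claim anatomical realism, and passing tests therefore validate the
*analysis chain*, not segmentation difficulty on real anatomy.

### The degradation model

`degrade_segmentation()` turns a reference segmentation into an
"automatic-like" one with a controlled error budget:
`error_fraction` (default 0.05) times the structure's foreground voxels at
each degraded phase. The budget is allocated multinomially over four slice
categories with structure-specific defaults taken from the observed
distribution of automatic-segmentation errors — RV: 30.7% basal, 61%
mid-ventricular, 5.4% apical, 2.9% beyond the extent; LV: 18.3% / 70% /
7.5% / 4.2%. Within the extent, errors are an even mixture of deletions
inside the structure and false-positive additions adjacent to it
(`addition_fraction = 0.5`); this keeps the degraded volume approximately
unbiased, so automatic phase selection remains stable — which is also why
a deletion-only model (`addition_fraction = 0`) is available for
experiments on biased automatic volumetry. Out-of-extent errors are
additions only (false negatives are impossible beyond the extent by
definition), split 70/30 between the slice above the base and the slice
below the apex. Degradation applies to the ED and ES phases by default
(the phases that feed clinical measurements); `all_phases = TRUE` extends
it to the whole cycle. If a category is geometrically impossible (e.g. a
single-slice structure has no distinct apical slice), its budget is
reallocated to the mid category with a warning.

## Measurements, phase selection, correction

Volumetry is plain voxel counting times voxel volume. ED is the phase of
maximal segmented volume and ES the phase of minimal volume, ties resolved
to the earliest phase; ED/ES are selected **per ventricle independently**
(the RV and LV reach their extremes at slightly different phases), with a
fixed phase pair available for the manual arm — on synthetic data the
"manually selected" phases are the generator's ground truth. The basal
slice of a CMR volume is the highest occupied slice in the union of both
structures across both segmentations at that phase (`scope = "volume"`,
with a per-structure scope available), and `apply_basal_correction()`
replaces exactly that slice with the reference at the listed phases,
touching nothing else. Body surface area uses Mosteller by default with
DuBois as an alternative; no particular indexing formula is canonical for
RVEDVI, so the choice is explicit and configurable.

## Task Force scoring

`classify_cmr()` encodes the rules above at full floating precision (no
rounding before threshold comparison), with major taking precedence when
both bands are hit and RWMA as a hard prerequisite. One wording ambiguity
exists in the literature for the female major cutoff (≥ 100 vs > 100
ml/m²); the package defaults to ≥ 100 and exposes
`tfc_thresholds(female_major_strict = TRUE)` for the strict reading — the
two differ only at exactly 100 ml/m². `total_tfc()` uses the simplified
diagnosis rule of summing points across categories against the 4-point
cutoff; the full 2010 rule about combining criteria from *different*
categories is out of scope and deliberately not implemented.

## Agreement statistics

* **Dice** is computed in 3D per structure and phase; two empty masks
  score 1 (agreement on absence — needed for degenerate synthetic
  slices), one empty mask scores 0.
* **Hausdorff distance** is the exact symmetric maximum over boundary
  voxels in physical millimetres (anisotropic spacing applied), not a 95th
  percentile. The inner max–min is a small compiled kernel with the
  standard early-break.
* **Error attribution** pools misclassified voxels over ED and ES and bins
  each by slice relative to the *reference* structure extent: top
  reference slice → basal, bottom → apical, interior → mid, beyond →
  outside.
* **Phase differences** are signed, wrapped circularly to half a cycle,
  and expressed as a percent of the cycle.
* **Bland–Altman** uses bias ± 1.96 × sample SD. Measurement agreement is
  reported as signed mean difference ± SD ("bias (SD)").
* **Pearson r** carries a Fisher-z 95% interval.
* **Cohen's κ** is unweighted over {none, minor, major} and reported with
  the large-sample standard error
  `sqrt(p_o (1 − p_o) / (n (1 − p_e)²))`; when both raters use a single
  identical category κ is undefined and perfect agreement is reported as 1
  with a warning.
* **McNemar** is exact-binomial on discordant pairs below 25 discordants,
  chi-square with continuity correction above.

Sensitivity and specificity are computed for two binarizations of the CMR
criterion — "at least minor" and "major" — against the definite-diagnosis
label of the manual arm.

## The toy segmentation stage

The optional network stage is a compact, CPU-scale dilated-convolution
segmenter written natively in R: a fixed random bank of 3×3 filters at
dilations 1/2/4 with a residual second stage produces per-pixel features
(including normalized in-plane coordinates, which the roughly centred
phantoms justify), and a trainable softmax head maps features to
background/LV/RV probabilities. Training uses minibatch Adam with analytic
gradients of the combined loss — mean cross-entropy plus one minus the
mean foreground soft-Dice. Both soft-Dice normalizations are implemented:
the conventional one with the factor 2 (the default; its loss is zero at a
perfect prediction) and an `as_printed` variant without it, whose maximum
is 0.5 at perfect overlap. Dropout (default 0.1) on the feature
activations makes the forward pass stochastic; Monte-Carlo-dropout
inference averages the softmax over 15 samples by default, and with
dropout 0 collapses exactly to a single deterministic pass. Predicted
label maps are post-processed by retaining the largest 3D connected
component per class (26-connectivity by default, for the strongly
anisotropic slices; 6-connectivity by flag), which can only remove voxels.
Augmentation covers 90° rotations and gamma transforms; elastic
deformation is omitted at this scale. The default learning rate (0.001
with ×0.1 step decay) mirrors a full-scale recipe tuned for very long
schedules; short toy runs (a few hundred iterations on 48–64 px phantoms)
converge faster at 0.01. Clinical-scale fidelity is explicitly out of
scope — the generator's degraded volumes stand in for network output in
the pipeline by default.

## Numerical and design choices

* Log probabilities are clamped at ε = 1e-7 inside the cross-entropy.
* Softmax rows are normalized after a max-shift; sums are within 1e-5 of 1.
* Ties in phase selection and component sizes resolve to the earliest
  index / lowest deterministic component id.
* All randomness flows from integer seeds below 2³¹; per-subject streams
  are decoupled by deriving one sub-seed per subject from the master seed,
  so cohorts regenerate bit-identically and volumes can be rebuilt on
  demand (`cohort_reference()`) instead of being held in memory.
* Constant images normalize to all zeros with a warning (the percentile
  window is degenerate).

## Problem sizes

The test suite runs on coarse grids (72×72, 8 slices, 12–14 phases,
~2.2 mm voxels) with cohorts of 6–40 subjects, which keeps the full suite
around a minute while exercising identical code paths. The acceptance
script uses the full default geometry (160×160, 12 slices, 25–40 phases,
1.11–1.45 mm) with 200 subjects and completes in a few minutes on one CPU.

## Limitations

Synthetic phantoms cannot certify performance on clinical images: the
published clinical-cohort Dice, Hausdorff, correlation and κ values
require the original private dataset and a fully trained network, and are
deliberately not reproduced here. What the synthetic pipeline does
establish is the correctness of every computational step around such a
model — the measurement identities, the rule engine at its printed
cutoffs, the agreement statistics against independent oracles, and the
directional effects of basal-slice correction.
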