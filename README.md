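# arvcmr

Synthetic cine CMR volumetry and 2010 Task Force Criteria (TFC)
classification for arrhythmogenic right ventricular cardiomyopathy (ARVC),
as a fully testable R pipeline.

ARVC is diagnosed by summing points over six criterion categories (minor =
1, major = 2; definite diagnosis at ≥ 4 points). The CMR category requires
a regional RV wall-motion abnormality (RWMA) **plus** a function or volume
criterion with sex-specific cutoffs:

| category | rule |
|---|---|
| major | RWMA and (RVEF ≤ 40% **or** RVEDVI ≥ 110 ml/m² (♂) / ≥ 100 ml/m² (♀)) |
| minor | RWMA and (40 < RVEF ≤ 45% **or** RVEDVI ∈ [100, 110) ml/m² (♂) / [90, 100) ml/m² (♀)) |

where RVEF = 100·(EDV − ESV)/EDV and RVEDVI = RVEDV / body surface area.
Automatic short-axis segmentation can supply EDV/ESV, but its errors
concentrate in the most basal slice; the pipeline therefore also simulates
the clinically proposed remedy — replacing the automatic segmentation of
the most basal slice with the manual reference ("automatic⁻ᵇᵃˢᵃˡ") — and
quantifies what that correction buys in overlap (3D Dice), boundary error
(exact 3D Hausdorff, mm), measurement agreement (Bland–Altman bias ± SD,
Pearson r), ED/ES phase agreement (percent of cycle, circularly wrapped),
and classification agreement (Cohen's κ, sensitivity/specificity, McNemar).

Because no clinical cohort is public, the package ships a first-class
synthetic generator: three subject groups (controls / at-risk / ARVC) with
group-dependent RV dilation and dysfunction, smooth unimodal volume
curves, disc/crescent LV/RV phantoms rasterized to exact voxel budgets,
and a degradation model that places segmentation errors across slice
locations with structure-specific defaults (RV: 30.7% basal, 61% mid,
5.4% apical, 2.9% outside the extent; LV: 18.3/70/7.5/4.2). A compact
dilated-convolution segmenter with Monte-Carlo-dropout inference and
largest-component post-processing is included for end-to-end experiments
on rendered phantom images.

Intended users: researchers prototyping CMR volumetry/criteria analyses
and anyone needing a reproducible, download-free benchmark for
segmentation-to-diagnosis pipelines.

## Worked example

```r
library(arvcmr)

# score one subject through the Task Force engine
score_tfc(tibble::tibble(
  sex = "female", rwma = TRUE,
  rvef_percent = 55, rvedvi_ml_m2 = 102, noncmr_points = 3L
))
#>   sex    rwma  rvef_percent rvedvi_ml_m2 noncmr_points cmr_category cmr_points
#> 1 female TRUE            55          102             3 major                 2
#> # total_points 5, definite_diagnosis TRUE
# at RVEDVI 97 the criterion drops to minor: 4 points, diagnosis unchanged

# a small end-to-end experiment: simulate -> degrade -> measure ->
# correct -> classify -> evaluate
cfg <- experiment_config(
  cohort = cohort_config(n_subjects = 20, shape = c(96, 96), n_slices = 10,
                         in_plane_range = c(1.8, 2.0),
                         n_phases_range = c(20, 25), seed = 7),
  seed = 7
)
ex <- run_experiment(cfg)
ex
#> <arvc_experiment> 20 subjects (0 failed), seed 7, 14.8 s
#>   kappa (automatic vs manual): 1.000 +/- 0.000
#>   kappa (automatic_minus_basal vs manual): 1.000 +/- 0.000

glance(ex)
#>   n_subjects n_failed mean_dice_auto mean_dice_corrected rv_basal_error_fraction
#> 1         20        0          0.975               0.976                   0.300

ex$agreement$attribution_summary
#>   structure basal   mid apical outside total_errors
#> 1 LV        0.190 0.693 0.0727  0.0437         6275
#> 2 RV        0.300 0.618 0.0537  0.0283         7711
```

The κ of 1 says every one of the 20 subjects kept its none/minor/major CMR
classification under the degraded automatic measurements at this error
level; the attribution table shows the degradation model concentrating RV
errors in the basal slice (30%) exactly as configured. `tidy(ex)` returns
the per-subject measurement table, `autoplot(ex)` the classification
transition matrix, and `write_report(ex, dir)` a Markdown/JSON report with
all agreement tables.

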