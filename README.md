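# nephrovol

Kidney volumetry from tomographic sections: estimator implementations,
synthetic phantom validation, and trial power analysis.

## Why

In autosomal dominant polycystic kidney disease (ADPKD), total kidney
volume (TKV) grows a few percent per year and is the imaging endpoint
drug trials hinge on. TKV can be measured by slice-by-slice **planimetry**
(trace every outline; volume = Σ area × slice thickness), **stereology**
(count random grid points on the organ), a one-slice **mid-slice**
shortcut (area × covering slices × thickness × 0.637/0.624 for
right/left), the **ellipsoid caliper formula**
(SKV = mean length × width × depth × π/6), or plain **kidney length**.
They differ enormously in effort and in precision, and the choice decides
how many patients a trial needs.

`nephrovol` implements all five estimators, validates them on synthetic
kidney phantoms with exact ground-truth volume (superellipsoid bases with
cyst-like surface bumps, voxelized or contoured under MR-like 4 mm
coronal or CT-like 5 mm axial geometry), emulates duplicate manual
tracings with a correlated boundary-noise model, and carries the
comparison through the statistics a methods study reports:
repeated-measures CV, Bland–Altman agreement, RMSE against the planimetry
reference, Pearson correlation, baseline-adjusted ANCOVA, unpaired
t-tests, and two-sample normal-approximation sample sizes.

## Worked example

```r
library(nephrovol)

# a 785 ml kidney-shaped ellipsoid, MR-like coronal sectioning
phantom <- kidney_phantom(ellipsoid_spec(c(50, 50, 75)))
geom    <- imaging_geometry("MR", in_plane_spacing = 2, matrix_size = 160L)

contours <- contour_stack(phantom, geom)
mask     <- voxelize(phantom, geom)

oracle_volume(phantom)                       # 785.3982  (ground truth, ml)
planimetry_volume(contours)$skv_ml           # 783.7448  (-0.21%)
stereology_volume(mask,
  stereology_grid(geom, seed = 1))$skv_ml    # 770.05  (one random grid)
midslice_volume(contours, "right")$skv_ml    # 718.91    (0.637 shortcut)
ellipsoid_method_volume(
  measure_axes(mask), "right")$skv_ml        # 751.50    (caliper formula)
kidney_length(mask)                          # 14.96     (cm)

# sample size per arm to detect the published treatment effect,
# from the printed percentage-change statistics (planimetry row)
sample_size(mean_treated = 2.57, mean_control = 6.72,
            sd_treated = 6.07, alpha = 0.05, power = 0.80)   # 34
```

Planimetry lands within a fraction of a percent of truth; the mid-slice
and caliper shortcuts are several percent low even on this benign shape —
on cyst-distorted phantoms (see `generate_cohort()`) their bias reaches
−10% to −15% and their test–retest CV grows to ~8%, which is why trials
using them would need about four times as many patients.

## The analyses

Three scripts under `analysis/` re-run the package's studies and write
tables to `results/`:

1. `01_sectioning_error.R` — how much error sectioning alone (4 mm MR /
   5 mm CT, random slice phase) puts into analytic planimetry of
   700–6600 ml ellipsoids: max |error| ≈ 0.06% / 0.07%, far inside the
   published 0.26% / 0.10% bounds.
2. `02_method_comparison.R` — a 30-phantom cohort, traced twice by two
   virtual raters, measured by all five methods; emits
   volume / reproducibility / agreement tables.
3. `03_validation_sample_size.R` — simulated two-arm trials (38/37
   patients) from the published per-method TKV-change statistics, ANCOVA
   and t-test p-values, a 200-seed power sweep, and the per-method
   sample-size ladder (34, 59, 135, 148).

The methods vignette (`vignettes/kidney-volumetry-methods.Rmd`) documents
the phantom model, the noise model and every numerical convention.

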