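# btvcal — adaptive threshold calibration for PET target volumes

Thresholding is the workhorse method for delineating the biological target
volume (BTV) on FDG-PET images in radiotherapy planning: the tumour contour
is the iso-intensity line at some percentage TS of the lesion's maximum
uptake. The right percentage is not a constant — it depends on the lesion's
contrast over background, on its size, and on how much the reconstruction
smooths the image. `btvcal` implements an adaptive thresholding method that
calibrates TS against exactly those quantities, so that one calibration per
scanner *model* (not per individual scanner, and not per site) suffices.

The calibration model is the linear form

    TS = B0 + B1 * A + B2 * (1 - 1/TBR) + B3 * FWHM + E

where `A` is the target's maximal cross-section area (mm²), `TBR` the
measured target-to-background ratio (maximum pixel in the target over the
mean of background ROIs), `FWHM` the width (mm) of the transaxial
post-reconstruction Gaussian filter, and `E` the error term. Predictors are
retained by stepwise forward selection with an F-to-enter of 4 and a
minimum R² increment of 0.01; model reliability is assessed by split-sample
cross-validation shrinkage (R² − R²\*, reliable below 0.10), and scanners
are compared with the coincident-regression-lines F test.

The package provides, end to end:

* **Phantom simulation** — a digital IEC-body-phantom with nine spheres
  (ID 6.5–57.4 mm) in a 3 kBq/mL background, imaged under a 3D Gaussian
  point-spread function, count-statistics noise scaled by emission scan
  duration (ESD), and 2D transaxial Gaussian post-filtering
  (`iec_phantom()`, `build_activity_map()`, `simulate_scan()`,
  `apply_transaxial_filter()`, `generate_experiment_grid()`).
* **Image analysis** — background ROIs, measured TBR, detectability, and
  the optimal-threshold search that matches the autocontoured cross
  section to the known sphere area within 10 mm², scanning TS in 1% steps
  (`background_mean()`, `measured_tbr()`, `find_optimal_ts()`,
  `build_records()`).
* **Calibration** — stepwise forward selection with partial-F entry,
  standardized coefficients and per-step R², plus shipped reference
  calibration equations for eight scanner models
  (`stepwise_forward()`, `predict_ts()`, `reference_model()`).
* **Validation** — split-sample shrinkage, holdout residual summaries, and
  the between-scanner coincidence test (`cross_validate()`,
  `residual_summary()`, `coincidence_test()`).
* **Segmentation** — applying a calibrated model to delineate a BTV on an
  image, including fixed-point iteration for area-dependent models
  (`delineate_btv()`, `area_model_iteration()`).

Results are tibbles throughout; fitted objects have `tidy()`/`glance()`
methods and `autoplot()` figures. A thin command-line front end lives in
`exec/btvcal` (subcommands `simulate`, `analyze`, `calibrate`, `predict`,
`validate`, `compare`, `segment`).

## Worked example

Predict the threshold for a head-and-neck lesion imaged on a Biograph
Hi-REZ, with measured TBR 12 and a 4 mm post-filter:

```r
library(btvcal)
predict_ts(reference_model("biograph_hirez"), tbr = 12, fwhm = 4)
#> # A tibble: 1 × 2
#>      ts ts_percent
#>   <dbl>      <int>
#> 1  39.4         39
```

A 39% threshold of the lesion maximum delineates the BTV.

Calibrating from scratch on the synthetic phantom (9 TBRs × 4 scan
durations × 3 post-filter widths, 96×96×24 grid at 2.7×2.7×3.3 mm voxels,
spheres above the 133 mm² size cutoff):

```r
grid <- generate_experiment_grid(
  iec_phantom(), tbrs = default_tbr_grid(), esds = c(2, 3, 4, 5),
  recons = list(recon_spec(6, 14), recon_spec(9, 14), recon_spec(13, 14)),
  dim = c(96, 96, 24), psf_fwhm = 6.3, noise_coeff = 0.25, master_seed = 2024)
records <- build_records(grid)
cal <- stepwise_forward(assemble_design(records))
cal
#> <ts_calibration> custom
#>   TS = 90.0398 -54.11*x2 +0.9251*x3_fwhm
#>   R^2 = 0.88, adj R^2 = 0.879
#>   selection order: x2 -> x3_fwhm
```

The simulated calibration reproduces the structure seen on real scanners:
contrast (`x2 = 1 - 1/TBR`) enters first with a large negative weight
(thresholds fall as contrast rises), the post-filter width enters second
with a positive weight (smoothing raises the required threshold), and the
scan duration never enters — noise widens the spread of TS but does not
shift it. Takes about a minute on a laptop-class core.

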