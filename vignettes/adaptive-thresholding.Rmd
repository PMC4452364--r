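---
title: "Adaptive threshold calibration for PET target volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive threshold calibration for PET target volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btvcal)
```

## The problem

A hot lesion on a PET image has no sharp edge: the scanner's point-spread
function (PSF) and the post-reconstruction smoothing turn the true
step-edged activity distribution into a smooth hill. Delineating the
biological target volume (BTV) by thresholding at a fixed percentage of the
lesion maximum therefore over- or under-estimates the true extent depending
on three things:

* **Contrast.** The higher the target-to-background ratio (TBR), the lower
  the percentage that lands the contour on the true boundary, because the
  boundary value is roughly midway between background and peak.
* **Size.** Targets small relative to the system resolution lose peak
  intensity to the partial-volume effect, which pushes the optimal
  threshold up.
* **Smoothing.** A wider transaxial post-filter both depresses the peak
  and broadens the edge, again raising the optimal threshold.

`btvcal` calibrates the optimal threshold TS (percent of the lesion
maximum whose autocontour recovers the true cross-section area) as a
linear function of these quantities:

$$\mathrm{TS} = B_0 + B_1 A + B_2\,(1 - 1/\mathrm{TBR}) + B_3\,\mathrm{FWHM} + E$$

with $A$ the maximal cross-section area in mm², the contrast entering
through $X_2 = 1 - 1/\mathrm{TBR}$ (bounded, linearising the hyperbolic
dependence on TBR), and FWHM the transaxial Gaussian post-filter width in
mm. The TBR used is the *measured* one — maximum pixel in an ROI
encircling the target over the mean of background ROIs — because that is
what is observable on a patient image; the nominal ratio is kept as
metadata only. Reconstruction parameters (FWHM, iteration number, axial
kernels, relaxation, TOF kernel width) are treated as known inputs: they
are settings of the reconstruction, never estimated from the image.

## The synthetic phantom

The simulator emulates an IEC body phantom sphere set: six spheres of
10–37 mm internal diameter on a coplanar ring (radius 57.2 mm), plus two
micro spheres (6.5, 8.1 mm) and one 57.4 mm sphere below the ring, in a
uniform 3 kBq/mL background, with sphere activity `TBR × background`. The
acquisition model is deliberately minimal:

1. **PSF blur** — isotropic 3D Gaussian, default FWHM 6.3 mm (a BGO
   whole-body scanner class value; the plausible range is about 4–7 mm).
2. **Noise** — zero-mean Gaussian per voxel with
   $\sigma = c\sqrt{a/\mathrm{ESD}}$, where $a$ is the blurred local
   activity and ESD the emission scan duration in minutes (protocol grid
   2–5 min). This mimics count statistics: variance proportional to local
   activity, inversely proportional to counting time. The amplitude
   default $c = 0.25$ gives roughly 10% relative noise in the background
   at 2 min before post-filtering, a realistic whole-body level. Under
   this model noise widens the spread of measured TS but does not shift
   its mean, which is why scan duration should not (and, in the tests,
   does not) survive predictor selection.
3. **Post-filter** — 2D Gaussian smoothing applied in the transaxial plane
   only, with the user's FWHM. Axial mean-filter kernels are carried as
   inert covariate labels, never simulated.

What the simulator does *not* contain: scatter, randoms, attenuation,
sinogram-level effects, time-of-flight or PSF-modelling reconstruction,
lesion motion, and heterogeneous uptake. Consequently, passing tests show
that the *method* (threshold search, selection, validation statistics)
behaves correctly and that the qualitative structure of real calibrations
(sign pattern, predictor ranking, ESD irrelevance) emerges from
partial-volume physics alone — they do not certify absolute threshold
levels for any real scanner. Real-scanner use should rely on the shipped
reference equations or on a phantom calibration of the actual device.

Each acquisition in a simulated protocol grid gets its own RNG seed drawn
deterministically from the master seed and recorded in the metadata, so
any single volume can be regenerated bit-identically.

## Image analysis

* **Background.** Six 17 mm-diameter circular ROIs on the central sphere
  plane; by default they sit on a 30 mm-radius ring midway between the
  sphere angles, safely outside every sphere (positions are
  configurable). BG is the mean over the union of ROI pixels, and its SD
  feeds the detectability rule.
* **Detectability.** A sphere is analysed only if its encircling-ROI
  maximum exceeds BG + 3·SD(BG). Visual detectability has no exact
  numeric equivalent; this conventional 3-sigma proxy makes the pipeline
  automatic, and the multiplier is a configuration knob. Skipped spheres
  are counted so that records + skipped always equals the theoretical
  number of observations.
* **Threshold search.** On the sphere's central slice (the slice plane
  nearest the centre), a square window of side ID + 12 mm is scanned at
  thresholds 1–100% of the window maximum in 1% steps. At each threshold
  the 8-connected component containing the maximum is the contour; its
  area is pixel count × pixel area (no sub-pixel polygonisation — one
  pixel is ≈ 7.3 mm² at the default 2.7 mm spacing, below the 10 mm²
  matching tolerance). The returned TS minimises |measured − true| area;
  ties break toward the larger threshold. This global argmin satisfies
  the "differs by less than 10 mm²" convergence criterion whenever any
  threshold does, and is deterministic where a directional scan would
  depend on its starting point. 8-connectivity avoids fragmenting
  contours at one-pixel necks.

The threshold search is verified against an independent oracle: for a
noiseless Gaussian-blurred disk the optimal threshold is the blurred
boundary intensity over the blurred peak intensity, computable to high
accuracy by Bessel-function quadrature. Across disks of 13–37 mm and
blurs of 4–11 mm FWHM the grid search agrees with this oracle within 2
percentage points (at 0.5 mm rasterisation, so that pixel quantisation
does not dominate the comparison).

## Calibration and validation

* **Selection.** Pure forward selection (no removal step): the candidate
  with the largest partial F enters while F > 4 *and* the multiple R²
  rises by ≥ 0.01. The F rule is applied as F-to-enter at the addition
  step. The ΔR² rule uses the multiple R², not the adjusted one —
  adjusted R² is reported separately as goodness of fit. Ties in F break
  by candidate order; a zero-variance candidate can never enter. The
  R² increment of the first entered variable is reported as its partial
  R², later increments as additional R². Records with cross-section area
  ≤ 133 mm² are excluded before fitting (severe volume-estimation errors
  below roughly twice the scanner FWHM; the cutoff corresponds to the
  13 mm sphere).
* **Reliability.** Random 50/50 split (the proportion is a package
  choice; the method only requires two groups): fit on training, predict
  holdout, shrinkage = R² − R²\* with R²\* the squared Pearson
  correlation of holdout predictions and observations. Below 0.10 counts
  as reliable; negative values are legitimate and reported as-is.
* **Between-scanner comparison.** The coincidence test pools two record
  sets and adds a scanner dummy plus its interactions with the first
  q − 1 predictors (default q = 3: separate intercept and slopes), and
  reports F = ΔSS/q/MS_full with the full model's residual df. The same
  formula evaluated on printed ANOVA quantities is exposed as
  `coincidence_f()` so published tables can be re-checked directly.
* **Prediction.** `predict_ts()` evaluates the equation and clips to the
  physical range [1, 100]%; it returns both the unrounded value and the
  nearest-integer percent. For models with an area term, prospective
  segmentation uses fixed-point iteration (`area_model_iteration()`):
  start from the area contoured at 50%, alternate prediction and
  contouring until the maximal cross-section area changes by < 1 mm².
  The 50% initialiser is a neutral midpoint; on simulated lesions the
  iteration contracts in a handful of steps, and a non-converged result
  is returned flagged rather than failing.

## Shipped reference models

`reference_models()` carries measured-data calibration equations for eight
scanner models (Discovery ST/STE/600/690, Biograph Hi-REZ/TRUEV, Gemini
XL/TF) with their R², shrinkage, standardized betas and per-step R². They
are shipped as data, not refit: their coefficients derive from multicenter
measurements on real hardware which a Gaussian-blur simulator cannot (and
should not claim to) reproduce. In this package they serve three roles:
lookup calibrations for `predict_ts()` and the segmentation front end;
generating truths for the synthetic record generator; and reference points
for the test suite. Where a published text quotes a Gemini TF TBR
coefficient of 59.3 while the corresponding table row reads 57.44, the
shipped data follows the table.

## Numerical choices and degenerate inputs

* Gaussian convolution is separable with mirror (half-sample symmetric)
  boundaries; per-slice total intensity is conserved to well under 0.1%
  for phantom-like images, and a zero FWHM is the exact identity.
* Sphere rasterisation is by voxel-centre membership, no anti-aliasing:
  the resulting area error is under one voxel layer and is absorbed by
  the 10 mm² matching tolerance.
* Noiseless, unblurred inputs give exact results (TBR equals the nominal
  ratio; a step-edge disk is recovered at any threshold above the
  background fraction, and the tie rule then returns 100%).
* `tolerance = 0` in the threshold search demands an exact pixel-area
  match and normally reports non-convergence — the flag, not an error.
* Out-of-domain segmentation inputs (TBR > 70, contoured area below
  133 mm²) warn rather than fail; a measured TBR below 1.2 is an
  "insufficient contrast" error because no threshold is meaningful there.

## Problem sizes used in the checks

The shipped tests run the full pipeline at desk scale: a 96×96×24 voxel
grid (2.7×2.7×3.3 mm) for the 9 TBR × 4 ESD × 3 FWHM protocol — 108
volumes, 540 above-cutoff records — and n = 1600 synthetic records for
the regression-level checks, 20 replicates per scanner model for
selection recovery. These sizes keep a full run in the low minutes while
leaving every statistical conclusion comfortably powered; the simulator
itself accepts the full 128×128×47 default grid.

## Known limitations

* The simulator's absolute threshold levels depend on its simplified
  physics; only their structure is transferable.
* TS is defined on the maximal cross section only, matching the
  calibration definition — there is no fully 3D threshold search.
* Heterogeneous-uptake lesions violate the uniform-sphere premise;
  threshold methods as a class are not designed for them.
* The coincidence test assumes a common model form for both scanners;
  comparing scanners whose selected predictors differ requires choosing
  the union form explicitly.
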