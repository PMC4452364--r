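Package: btvcal
Title: Adaptive Threshold Calibration for PET Biological Target Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating and applying adaptive thresholding methods
    for biological target volume (BTV) delineation on PET images. Includes a
    synthetic NEMA-IEC-style phantom simulator (Gaussian point-spread blur,
    count-statistics noise, transaxial post-reconstruction smoothing), an
    automated optimal-threshold search that matches contoured cross sections
    to known sphere areas, stepwise multiple-regression calibration of the
    threshold on target-to-background ratio, cross-section area and
    post-filter width, split-sample reliability (shrinkage) analysis, a
    coincident-regression-lines test for between-scanner comparison, and a
    segmentation front-end that applies a calibrated model to delineate a
    target volume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
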