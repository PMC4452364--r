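#' Simulate measurement records from a known calibration equation
#'
#' Generates a synthetic measurement table whose threshold values follow a
#' given calibration equation plus zero-mean Gaussian noise, with the noise
#' standard deviation chosen so that the linear model explains a target
#' fraction of the variance. Predictors are drawn uniformly from the
#' standard protocol grids: TBR from the nine-point protocol, post-filter
#' FWHM from `fwhm_grid` (a single constant when the equation has no FWHM
#' term, mirroring scanners without a user-settable transaxial filter), and
#' the true cross-section areas of the spheres above the size cutoff.
#' Emission scan duration and EM-equivalent iteration number are included
#' as inert columns (they never enter the generating equation) so that
#' selection procedures can be exercised against decoy predictors.
#'
#' @param model A `ts_calibration` used as the generating truth (e.g.
#'   [reference_model()]).
#' @param n Number of records.
#' @param target_r2 Fraction of response variance explained by the signal;
#'   the noise SD is set to `sd(signal) * sqrt((1 - target_r2) / target_r2)`.
#' @param seed Integer seed.
#' @param tbr_grid,fwhm_grid,area_grid,esd_grid,iter_grid Value grids the
#'   predictors are sampled from.
#' @return A tibble with columns `x1_area`, `tbr_nominal`, `tbr_measured`,
#'   `x2`, `x3_fwhm`, `esd`, `em_iterations`, `ts`, plus attribute
#'   `"noise_sd"`.
#' @export
simulate_calibration_records <- function(model, n = 1600, target_r2 = 0.85,
                                         seed = 1L,
                                         tbr_grid = default_tbr_grid(),
                                         fwhm_grid = c(4, 6, 8, 11),
                                         area_grid = NULL,
                                         esd_grid = c(2, 3, 4, 5),
                                         iter_grid = c(16, 24, 32, 48)) {
  stopifnot(inherits(model, "ts_calibration"))
  if (target_r2 <= 0 || target_r2 >= 1) abort("`target_r2` must be in (0, 1).")
  if (is.null(area_grid)) {
    ids <- iec_sphere_ids()
    area_grid <- pi * (ids[ids > 13] / 2)^2  # spheres above the 133 mm^2 cutoff
  }
  terms <- names(model$coefficients)
  if (!("x3_fwhm" %in% terms)) fwhm_grid <- fwhm_grid[1]
  withr::with_seed(seed, {
    tbr <- sample(tbr_grid, n, replace = TRUE)
    fwhm <- sample(fwhm_grid, n, replace = TRUE)
    area <- sample(area_grid, n, replace = TRUE)
    esd <- sample(esd_grid, n, replace = TRUE)
    iters <- sample(iter_grid, n, replace = TRUE)
    # raw linear predictor (no clipping): the generating equation is linear
    coefs <- model$coefficients
    signal <- coefs[["(Intercept)"]] +
      (if ("x1_area" %in% names(coefs)) coefs[["x1_area"]] * area else 0) +
      coefs[["x2"]] * (1 - 1 / tbr) +
      (if ("x3_fwhm" %in% names(coefs)) coefs[["x3_fwhm"]] * fwhm else 0)
    noise_sd <- stats::sd(signal) * sqrt((1 - target_r2) / target_r2)
    out <- tibble(
      x1_area = area,
      tbr_nominal = tbr,
      tbr_measured = tbr,
      x2 = 1 - 1 / tbr,
      x3_fwhm = fwhm,
      esd = esd,
      em_iterations = iters,
      ts = signal + rnorm(n, 0, noise_sd)
    )
    attr(out, "noise_sd") <- noise_sd
    out
  })
}
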