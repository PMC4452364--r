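#' Shipped scanner-model calibration equations
#'
#' Reference calibration curves for eight PET/CT scanner models from a
#' multicenter phantom study, of the form
#' `TS = B0 + B1*A + B2*(1 - 1/TBR) + B3*FWHM` (terms absent where the
#' predictor never entered the model). These are measured-data calibrations
#' shipped as package data; they are not refit by this package.
#'
#' @return `reference_models()`: a tibble with one row per scanner model
#'   (coefficients, multiple R-squared, cross-validation shrinkage,
#'   selection order, standardized betas and per-step R-squared).
#' @examples
#' reference_models()$model_id
#' reference_model("discovery_st")
#' @export
reference_models <- function() {
  path <- system.file("extdata", "reference_models.tsv", package = "btvcal",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname reference_models
#' @param model_id One of the `model_id` values of [reference_models()]
#'   (e.g. `"discovery_st"`, `"biograph_hirez"`, `"gemini_tf"`).
#' @return `reference_model()`: a `ts_calibration` ready for [predict_ts()].
#' @export
reference_model <- function(model_id) {
  tab <- reference_models()
  row <- tab[tab$model_id == model_id, ]
  if (nrow(row) != 1L) {
    abort(paste0("unknown model_id '", model_id, "'; available: ",
                 paste(tab$model_id, collapse = ", ")))
  }
  coefs <- c("(Intercept)" = row$b0)
  if (!is.na(row$b1_area)) coefs["x1_area"] <- row$b1_area
  coefs["x2"] <- row$b2_tbr
  if (!is.na(row$b3_fwhm)) coefs["x3_fwhm"] <- row$b3_fwhm
  order <- strsplit(row$selection_order, ";")[[1]]
  beta <- c(x2 = row$beta_x2, x3_fwhm = row$beta_x3, x1_area = row$beta_x1)
  pr2 <- c(x2 = row$pr2_x2, x3_fwhm = row$pr2_x3, x1_area = row$pr2_x1)
  new_ts_calibration(
    scanner_model = row$label,
    coefficients = coefs,
    selection_order = order,
    r_squared = row$r_squared,
    std_beta = beta[order],
    partial_r2 = pr2[order],
    shrinkage = row$shrinkage
  )
}
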