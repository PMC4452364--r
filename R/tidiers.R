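#' Tidy a least-squares threshold fit
#'
#' @param x A `ts_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`.
#' @export
tidy.ts_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm),
         estimate = sm[, 1],
         std_error = sm[, 2],
         statistic = sm[, 3],
         p_value = sm[, 4])
}

#' @rdname tidy.ts_fit
#' @return `glance()`: a one-row tibble of fit statistics (R-squared,
#'   adjusted R-squared, residual SD, SS decomposition, degrees of freedom).
#' @export
glance.ts_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared,
         adj_r_squared = x$adj_r_squared,
         sigma = x$sigma,
         ss_regression = x$ss_regression,
         ss_residual = x$ss_residual,
         ss_total = x$ss_total,
         df_regression = x$df_regression,
         df_residual = x$df_residual,
         n = x$n)
}

#' Tidy a threshold calibration model
#'
#' @param x A `ts_calibration`.
#' @param ... Unused.
#' @return One row per model term: `term`, `estimate`, `std_beta`,
#'   `partial_r2` (the R-squared increment when the term entered), `step`.
#' @export
tidy.ts_calibration <- function(x, ...) {
  terms <- names(x$coefficients)
  ord <- x$selection_order
  tibble(term = terms,
         estimate = unname(x$coefficients),
         std_beta = unname(x$std_beta[terms]),
         partial_r2 = unname(x$partial_r2[terms]),
         step = match(terms, ord))
}

#' @rdname tidy.ts_calibration
#' @export
glance.ts_calibration <- function(x, ...) {
  tibble(scanner_model = x$scanner_model,
         r_squared = x$r_squared,
         adj_r_squared = x$adj_r_squared,
         residual_sd = x$residual_sd,
         shrinkage = x$shrinkage,
         n_predictors = length(x$selection_order),
         n = x$n)
}
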