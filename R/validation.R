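#' Random split into training and holdout groups
#'
#' @param data A data frame with at least 20 rows.
#' @param fraction Fraction assigned to the training group (0 < f < 1);
#'   `round(fraction * n)` rows are sampled without replacement.
#' @param seed Integer seed making the partition reproducible.
#' @return A list with tibbles `training` and `holdout` (disjoint,
#'   exhaustive).
#' @export
split_sample <- function(data, fraction = 0.5, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  n <- nrow(data)
  if (n < 20) abort("need at least 20 observations to split.")
  idx <- withr::with_seed(seed, sample.int(n, round(fraction * n)))
  list(training = as_tibble(data[idx, , drop = FALSE]),
       holdout = as_tibble(data[-idx, , drop = FALSE]))
}

#' Split-sample cross-validation shrinkage
#'
#' Fits the model on a random training half, predicts the holdout half,
#' and reports the shrinkage `R^2 - R^2*`, where `R^2` is the training
#' multiple R-squared and `R^2*` the squared Pearson correlation between
#' holdout predictions and observations. Shrinkage below 0.10 is taken as
#' indicative of a reliable model; negative shrinkage can occur and is
#' reported as-is.
#'
#' @param data Design tibble.
#' @param predictors Character vector of predictor columns.
#' @param response Response column (default `"ts"`).
#' @param fraction Training fraction (default 0.5).
#' @param seed Split seed.
#' @param reliable_below Shrinkage threshold for the `reliable` flag.
#' @return An object of class `reliability_result`: a one-row tibble with
#'   `r2_training`, `r2_holdout`, `shrinkage`, `reliable`, `split_seed`,
#'   `n_training`, `n_holdout`; the training `ts_fit` is attached as
#'   attribute `"fit"` and the holdout residuals as `"holdout_residuals"`.
#' @export
cross_validate <- function(data, predictors, response = "ts", fraction = 0.5,
                           seed = 1L, reliable_below = 0.10) {
  halves <- split_sample(data, fraction = fraction, seed = seed)
  fit <- ols_fit(halves$training, response, predictors)
  pred <- stats::predict(fit$fit, newdata = halves$holdout)
  obs <- halves$holdout[[response]]
  r2_star <- stats::cor(pred, obs)^2
  shrink <- fit$r_squared - r2_star
  out <- tibble(r2_training = fit$r_squared,
                r2_holdout = r2_star,
                shrinkage = shrink,
                reliable = shrink < reliable_below,
                split_seed = seed,
                n_training = fit$n,
                n_holdout = length(obs))
  attr(out, "fit") <- fit
  attr(out, "holdout_residuals") <- obs - pred
  class(out) <- c("reliability_result", class(out))
  out
}

#' Tukey box-and-whisker summary of holdout residuals
#'
#' Descriptive statistics of the difference scores
#' `TS_observed - TS_predicted` (holdout cases scored with the training
#' equation): median, hinges, 1.5 IQR whisker bounds, and the number of
#' points beyond the whiskers.
#'
#' @param predicted,observed Equal-length numeric vectors (n >= 4).
#' @return An object of class `residual_summary`: a one-row tibble with
#'   `median`, `q1`, `q3`, `whisker_low`, `whisker_high`, `n_outliers`,
#'   `n`; the residual vector is attached as attribute `"residuals"`.
#' @export
residual_summary <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    abort("`predicted` and `observed` must have equal length.")
  }
  if (length(observed) < 4) abort("need at least 4 cases.")
  res <- observed - predicted
  bs <- grDevices::boxplot.stats(res)
  out <- tibble(median = bs$stats[3],
                q1 = bs$stats[2],
                q3 = bs$stats[4],
                whisker_low = bs$stats[1],
                whisker_high = bs$stats[5],
                n_outliers = length(bs$out),
                n = length(res))
  attr(out, "residuals") <- res
  class(out) <- c("residual_summary", class(out))
  out
}

# F statistic for coincident regression lines from sums of squares
coincidence_f_stat <- function(ss_res_reduced, ss_res_full, ms_res_full, q,
                               df_full) {
  f <- (ss_res_reduced - ss_res_full) / q / ms_res_full
  tibble(f_statistic = f, df1 = q, df2 = df_full,
         p_value = pf(f, q, df_full, lower.tail = FALSE))
}

#' Coincident-regression-lines F statistic from printed sums of squares
#'
#' Computes `F = (SS_res,reduced - SS_res,full) / q / MS_res,full` directly
#' from reported analysis-of-variance quantities, e.g. to re-evaluate a
#' published between-scanner comparison table.
#'
#' @param ss_res_reduced,ss_res_full Residual sums of squares of the pooled
#'   model without and with the scanner term.
#' @param ms_res_full Residual mean square of the full model.
#' @param q Number of extra parameters the F ratio is scaled by (default 3).
#' @param df_full Residual degrees of freedom of the full model; defaults to
#'   `ss_res_full / ms_res_full`.
#' @return A one-row tibble: `f_statistic`, `df1`, `df2`, `p_value`.
#' @examples
#' coincidence_f(28980.3, 28950.6, 13.48)
#' @export
coincidence_f <- function(ss_res_reduced, ss_res_full, ms_res_full, q = 3,
                          df_full = NULL) {
  if (is.null(df_full)) df_full <- round(ss_res_full / ms_res_full)
  coincidence_f_stat(ss_res_reduced, ss_res_full, ms_res_full, q, df_full)
}

#' Test of coincident regression lines between two scanners
#'
#' Pools the records of two scanners and compares a reduced model (common
#' calibration line) with a full model in which a dummy variable coding the
#' scanner enters, together with its interactions with the first `q - 1`
#' predictors (so the full model spends `q` extra parameters: separate
#' intercept and slopes). A small F means there is no statistical basis for
#' believing the two calibration lines differ.
#'
#' The printed-convention statistic divides the SS difference by `q`
#' regardless of the residual-df difference; since the full model here
#' genuinely adds `q` parameters, the same value is also the
#' degrees-of-freedom-consistent statistic.
#'
#' @param records_a,records_b Measurement record tibbles for the two
#'   scanners.
#' @param predictors Character vector naming the common model form.
#' @param response Response column (default `"ts"`).
#' @param q Number of extra parameters in the full model: 1 = intercept
#'   dummy only; `q > 1` adds interactions with the first `q - 1`
#'   predictors (default 3).
#' @return An object of class `coincidence_result`: a one-row tibble with
#'   `f_statistic`, `df1`, `df2`, `p_value`, `dummy_additional_r2`,
#'   `ss_res_reduced`, `ss_res_full`, `ms_res_full`; the two `ts_fit`
#'   objects are attached as attributes `"reduced"` and `"full"`.
#' @export
coincidence_test <- function(records_a, records_b, predictors,
                             response = "ts", q = 3) {
  if (nrow(records_a) == 0 || nrow(records_b) == 0) {
    abort("both record sets must be non-empty.")
  }
  common <- c(response, predictors)
  missing_a <- setdiff(common, names(records_a))
  missing_b <- setdiff(common, names(records_b))
  if (length(missing_a) || length(missing_b)) {
    abort("the two record sets do not share the model form columns.")
  }
  if (q < 1 || q > length(predictors) + 1) {
    abort("`q` must be between 1 and length(predictors) + 1.")
  }
  pooled <- dplyr::bind_rows(
    dplyr::mutate(records_a[common], .scanner = 0),
    dplyr::mutate(records_b[common], .scanner = 1)
  )
  reduced <- ols_fit(pooled, response, predictors)
  extra <- ".scanner"
  if (q > 1) {
    for (p in predictors[seq_len(q - 1)]) {
      nm <- paste0(".scanner_x_", p)
      pooled[[nm]] <- pooled$.scanner * pooled[[p]]
      extra <- c(extra, nm)
    }
  }
  full <- ols_fit(pooled, response, c(predictors, extra))
  stat <- coincidence_f_stat(reduced$ss_residual, full$ss_residual,
                             full$ms_residual, q, full$df_residual)
  out <- dplyr::bind_cols(stat, tibble(
    dummy_additional_r2 = full$r_squared - reduced$r_squared,
    ss_res_reduced = reduced$ss_residual,
    ss_res_full = full$ss_residual,
    ms_res_full = full$ms_residual
  ))
  attr(out, "reduced") <- reduced
  attr(out, "full") <- full
  class(out) <- c("coincidence_result", class(out))
  out
}
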