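#' Assemble the calibration design table
#'
#' Restricts the measurement records to targets in the clinically relevant
#' size range by dropping rows with true cross-section area at or below
#' `min_area` (default 133 mm^2, i.e. spheres larger than 13 mm ID — about
#' twice a typical scanner FWHM). The number of removed rows is attached as
#' attribute `"removed"`.
#'
#' @param records Measurement records from [build_records()].
#' @param min_area Area cutoff in mm^2.
#' @return The filtered tibble (design rows: predictors plus response `ts`).
#' @export
assemble_design <- function(records, min_area = 133) {
  if (nrow(records) == 0) abort("`records` is empty.")
  out <- dplyr::filter(records, .data$x1_area > min_area)
  if (nrow(out) == 0) abort("all rows removed by the area cutoff.")
  attr(out, "removed") <- nrow(records) - nrow(out)
  out
}

new_ts_fit <- function(fit, data, response, predictors) {
  y <- data[[response]]
  n <- length(y)
  res <- stats::residuals(fit)
  ss_total <- sum((y - mean(y))^2)
  ss_residual <- sum(res^2)
  ss_regression <- ss_total - ss_residual
  p <- length(predictors)
  df_regression <- p
  df_residual <- n - p - 1L
  structure(list(
    fit = fit,
    response = response,
    predictors = predictors,
    coefficients = coef(fit),
    n = n,
    ss_total = ss_total,
    ss_regression = ss_regression,
    ss_residual = ss_residual,
    df_regression = df_regression,
    df_residual = df_residual,
    ms_regression = if (df_regression > 0) ss_regression / df_regression else NA_real_,
    ms_residual = ss_residual / df_residual,
    r_squared = if (ss_total > 0) 1 - ss_residual / ss_total else NA_real_,
    adj_r_squared = if (ss_total > 0)
      1 - (ss_residual / df_residual) / (ss_total / (n - 1)) else NA_real_,
    sigma = sqrt(ss_residual / df_residual)
  ), class = "ts_fit")
}

#' Ordinary least-squares fit with sum-of-squares decomposition
#'
#' Fits `response ~ predictors` by least squares and reports the classical
#' ANOVA decomposition (regression and residual sums of squares, degrees of
#' freedom, mean squares) along with the multiple and adjusted R-squared.
#'
#' @param data A data frame of observations.
#' @param response Name of the response column (default `"ts"`).
#' @param predictors Character vector of predictor column names (may be
#'   empty for an intercept-only fit).
#' @return An object of class `ts_fit`.
#' @examples
#' d <- tibble::tibble(x = 1:10, ts = 5 + 2 * (1:10))
#' ols_fit(d, "ts", "x")$coefficients
#' @export
ols_fit <- function(data, response = "ts", predictors = character()) {
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols)) {
    abort(paste0("columns not found: ", paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(data)
  if (n <= length(predictors) + 1L) {
    abort("need more observations than coefficients.")
  }
  fml <- if (length(predictors)) {
    stats::reformulate(predictors, response = response)
  } else {
    stats::reformulate("1", response = response)
  }
  fit <- lm(fml, data = data)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("rank-deficient design; offending columns: ",
                 paste(bad, collapse = ", ")))
  }
  new_ts_fit(fit, data, response, predictors)
}

#' @export
print.ts_fit <- function(x, ...) {
  cat("<ts_fit> ", x$response, " ~ ",
      if (length(x$predictors)) paste(x$predictors, collapse = " + ") else "1",
      "\n  n = ", x$n, ", R^2 = ", signif(x$r_squared, 4),
      ", adj R^2 = ", signif(x$adj_r_squared, 4),
      ", residual SD = ", signif(x$sigma, 4), "\n", sep = "")
  print(signif(x$coefficients, 6))
  invisible(x)
}

#' Partial F statistic for adding one predictor
#'
#' The F-to-enter criterion of forward selection: the drop in residual sum
#' of squares from adding a single predictor, divided by the candidate
#' model's residual mean square. Equals the squared t statistic of the
#' added coefficient.
#'
#' @param current A `ts_fit` (the smaller model).
#' @param candidate A `ts_fit` nesting `current` with exactly one extra
#'   predictor, fitted to the same data.
#' @return A one-row tibble: `predictor_added`, `f_statistic`, `df1`, `df2`,
#'   `p_value`.
#' @export
partial_f <- function(current, candidate) {
  stopifnot(inherits(current, "ts_fit"), inherits(candidate, "ts_fit"))
  extra <- setdiff(candidate$predictors, current$predictors)
  if (length(extra) != 1L || !all(current$predictors %in% candidate$predictors) ||
      current$n != candidate$n || current$response != candidate$response) {
    abort("`candidate` must nest `current` with exactly one extra predictor.")
  }
  f <- (current$ss_residual - candidate$ss_residual) / candidate$ms_residual
  tibble(predictor_added = extra,
         f_statistic = f,
         df1 = 1L,
         df2 = candidate$df_residual,
         p_value = pf(f, 1, candidate$df_residual, lower.tail = FALSE))
}

#' Standardized regression coefficients
#'
#' `beta_i = B_i * SD(x_i) / SD(y)`: the coefficients the model would have
#' if every variable were scaled to unit variance, used to rank predictors
#' by their weight in explaining the response.
#'
#' @param model A `ts_fit` or `ts_calibration`.
#' @param data The dataset the model was fitted to (or one with the same
#'   columns).
#' @return Named numeric vector of standardized coefficients, one per
#'   non-intercept predictor.
#' @export
standardized_coeffs <- function(model, data) {
  if (inherits(model, "ts_calibration")) {
    preds <- model$selection_order
    coefs <- model$coefficients[preds]
    response <- model$response %||% "ts"
  } else {
    preds <- model$predictors
    coefs <- model$coefficients[preds]
    response <- model$response
  }
  sy <- stats::sd(data[[response]])
  if (!is.finite(sy) || sy == 0) abort("response has zero variance.")
  vapply(seq_along(preds), function(i) {
    coefs[[i]] * stats::sd(data[[preds[i]]]) / sy
  }, numeric(1)) |> setNames(preds)
}

new_ts_calibration <- function(scanner_model, coefficients, selection_order,
                               r_squared, adj_r_squared = NA_real_,
                               std_beta = NULL, partial_r2 = NULL,
                               residual_sd = NA_real_, shrinkage = NA_real_,
                               n = NA_integer_, steps = NULL, fit = NULL,
                               response = "ts") {
  structure(list(scanner_model = scanner_model,
                 coefficients = coefficients,
                 selection_order = selection_order,
                 r_squared = r_squared,
                 adj_r_squared = adj_r_squared,
                 std_beta = std_beta,
                 partial_r2 = partial_r2,
                 residual_sd = residual_sd,
                 shrinkage = shrinkage,
                 n = n,
                 steps = steps,
                 fit = fit,
                 response = response),
            class = "ts_calibration")
}

#' @export
print.ts_calibration <- function(x, ...) {
  terms <- names(x$coefficients)
  rhs <- sprintf("%+.4g*%s", x$coefficients[terms != "(Intercept)"],
                 terms[terms != "(Intercept)"])
  cat("<ts_calibration> ", x$scanner_model, "\n  TS = ",
      signif(x$coefficients[["(Intercept)"]], 6),
      if (length(rhs)) paste0(" ", paste(rhs, collapse = " ")) else "",
      "\n", sep = "")
  cat("  R^2 = ", signif(x$r_squared, 3),
      if (!is.na(x$adj_r_squared)) paste0(", adj R^2 = ", signif(x$adj_r_squared, 3)),
      if (!is.na(x$shrinkage)) paste0(", shrinkage = ", signif(x$shrinkage, 3)),
      "\n", sep = "")
  if (length(x$selection_order)) {
    cat("  selection order: ", paste(x$selection_order, collapse = " -> "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Stepwise forward selection of threshold predictors
#'
#' Builds the calibration model by pure forward selection: at each step the
#' candidate with the highest partial F enters, provided `F > f_enter` and
#' the multiple R-squared increases by at least `min_delta_r2`; otherwise
#' selection stops. The per-step R-squared increment is recorded (the
#' "partial R^2" of the first entered variable, the "additional R^2" of the
#' later ones), along with standardized coefficients of the retained
#' predictors. Equal-F ties break by candidate list order. There is no
#' removal step.
#'
#' @param data Design tibble (e.g. from [assemble_design()]).
#' @param response Response column name (default `"ts"`).
#' @param candidates Character vector of candidate predictor columns;
#'   defaults to the standard set present in the data (`x1_area`, `x2`,
#'   `x3_fwhm`, `esd`, `em_iterations`).
#' @param f_enter F-to-enter threshold (default 4).
#' @param min_delta_r2 Minimum R-squared increment (default 0.01).
#' @param scanner_model Label stored in the model.
#' @return A `ts_calibration`. With no viable candidate the model is
#'   intercept-only.
#' @export
stepwise_forward <- function(data, response = "ts", candidates = NULL,
                             f_enter = 4, min_delta_r2 = 0.01,
                             scanner_model = "custom") {
  if (is.null(candidates)) {
    candidates <- intersect(c("x1_area", "x2", "x3_fwhm", "esd",
                              "em_iterations"), names(data))
  }
  if (!length(candidates)) abort("no candidate predictors supplied.")
  current <- ols_fit(data, response, character())
  remaining <- candidates
  steps <- list()
  repeat {
    if (!length(remaining)) break
    trials <- purrr::map(remaining, function(cand) {
      fit <- tryCatch(ols_fit(data, response, c(current$predictors, cand)),
                      error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      list(cand = cand, fit = fit,
           f = partial_f(current, fit)$f_statistic,
           delta_r2 = fit$r_squared - max(current$r_squared, 0, na.rm = TRUE))
    })
    trials <- purrr::compact(trials)
    if (!length(trials)) break
    fs <- vapply(trials, function(t) t$f, numeric(1))
    best <- trials[[which.max(fs)]]  # first max: ties break by list order
    if (!is.finite(best$f) || best$f <= f_enter || best$delta_r2 < min_delta_r2) break
    steps[[best$cand]] <- list(predictor = best$cand, f = best$f,
                               delta_r2 = best$delta_r2,
                               r_squared = best$fit$r_squared)
    current <- best$fit
    remaining <- setdiff(remaining, best$cand)
  }
  order <- names(steps) %||% character(0)
  partial_r2 <- vapply(steps, function(s) s$delta_r2, numeric(1))
  std_beta <- if (length(order)) standardized_coeffs(current, data) else NULL
  new_ts_calibration(
    scanner_model = scanner_model,
    coefficients = current$coefficients,
    selection_order = order,
    r_squared = current$r_squared,
    adj_r_squared = current$adj_r_squared,
    std_beta = std_beta,
    partial_r2 = if (length(order)) setNames(partial_r2, order) else NULL,
    residual_sd = current$sigma,
    n = current$n,
    steps = steps,
    fit = current,
    response = response
  )
}

#' Predict the optimal threshold from a calibration model
#'
#' Evaluates `TS = B0 + B1*A + B2*(1 - 1/TBR) + B3*FWHM (+ extras)` and
#' clips the result to the physical range [1, 100] percent. Only the
#' predictors present in the model are required: models without an area
#' term need no `area`, and so on.
#'
#' @param model A `ts_calibration` (fitted or from [reference_model()]).
#' @param tbr Measured target-to-background ratio(s), >= 1.
#' @param area Target cross-section area(s), mm^2 (required when the model
#'   has an `x1_area` term).
#' @param fwhm Transaxial post-filter FWHM (mm) of the reconstruction
#'   (required when the model has an `x3_fwhm` term).
#' @param extras Named list of values for any further model terms.
#' @return A tibble with one row per input: `ts` (unrounded, clipped to
#'   [1, 100]) and `ts_percent` (nearest integer percent).
#' @examples
#' predict_ts(reference_model("biograph_hirez"), tbr = 12, fwhm = 4)
#' @export
predict_ts <- function(model, tbr, area = NULL, fwhm = NULL, extras = list()) {
  stopifnot(inherits(model, "ts_calibration"))
  if (any(tbr < 1)) abort("`tbr` must be >= 1.")
  supplied <- c(list(x2 = 1 - 1 / tbr),
                if (!is.null(area)) list(x1_area = area),
                if (!is.null(fwhm)) list(x3_fwhm = fwhm),
                extras)
  terms <- setdiff(names(model$coefficients), "(Intercept)")
  missing_terms <- setdiff(terms, names(supplied))
  if (length(missing_terms)) {
    abort(paste0("model requires predictor(s) not supplied: ",
                 paste(missing_terms, collapse = ", ")))
  }
  vals <- purrr::map(terms, ~ supplied[[.x]])
  ts <- model$coefficients[["(Intercept)"]]
  for (i in seq_along(terms)) {
    ts <- ts + model$coefficients[[terms[i]]] * vals[[i]]
  }
  ts <- pmin(pmax(ts, 1), 100)
  tibble(ts = ts, ts_percent = as.integer(round(ts)))
}

#' Read and write calibration model files
#'
#' Models are stored as structured text (YAML): label, coefficient map,
#' selection order and fit statistics.
#'
#' @param model A `ts_calibration`.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   `ts_calibration`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ts_calibration"))
  ser <- list(scanner_model = model$scanner_model,
              coefficients = as.list(model$coefficients),
              selection_order = as.list(model$selection_order),
              r_squared = model$r_squared,
              adj_r_squared = model$adj_r_squared,
              std_beta = as.list(model$std_beta),
              partial_r2 = as.list(model$partial_r2),
              residual_sd = model$residual_sd,
              shrinkage = model$shrinkage,
              n = model$n)
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  ser <- yaml::read_yaml(path)
  new_ts_calibration(
    scanner_model = ser$scanner_model,
    coefficients = unlist(ser$coefficients),
    selection_order = as.character(unlist(ser$selection_order)),
    r_squared = ser$r_squared %||% NA_real_,
    adj_r_squared = ser$adj_r_squared %||% NA_real_,
    std_beta = if (length(ser$std_beta)) unlist(ser$std_beta),
    partial_r2 = if (length(ser$partial_r2)) unlist(ser$partial_r2),
    residual_sd = ser$residual_sd %||% NA_real_,
    shrinkage = ser$shrinkage %||% NA_real_,
    n = ser$n %||% NA_integer_
  )
}
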