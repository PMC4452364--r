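test_that("the design table applies the clinical size cutoff", {
  rec <- tibble::tibble(
    x1_area = pi * (c(10, 13, 17, 22) / 2)^2,
    x2 = 1 - 1 / c(2.5, 8, 25, 70),
    x3_fwhm = c(6, 9, 6, 9), ts = c(70, 60, 50, 45)
  )
  d <- assemble_design(rec)
  expect_equal(nrow(d), 2)  # 10 and 13 mm (78.5, 132.7 mm^2) fall at/below 133
  expect_equal(attr(d, "removed"), 2)
  expect_error(assemble_design(rec[1:2, ]), "all rows removed")
  expect_equal(assemble_design(rec, min_area = 0), rec, ignore_attr = TRUE)
  expect_equal((1 - 1 / 2.5), 0.6)
  expect_true(all(1 - 1 / default_tbr_grid() >= 0.6 &
                    1 - 1 / default_tbr_grid() <= 0.9857143))
})

test_that("least squares reproduces exact data and the normal equations", {
  d <- tibble::tibble(x = as.numeric(1:10), ts = 5 + 2 * (1:10))
  fit <- ols_fit(d, "ts", "x")
  expect_equal(unname(fit$coefficients), c(5, 2), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  set.seed(17)
  dd <- tibble::tibble(a = rnorm(60), b = runif(60), c = rnorm(60))
  dd$ts <- 3 + 1.5 * dd$a - 2 * dd$b + rnorm(60)
  fit2 <- ols_fit(dd, "ts", c("a", "b", "c"))
  X <- cbind(1, dd$a, dd$b, dd$c)
  oracle <- solve(crossprod(X), crossprod(X, dd$ts))
  expect_equal(unname(fit2$coefficients), as.vector(oracle), tolerance = 1e-8)
  expect_equal(fit2$ss_total, fit2$ss_regression + fit2$ss_residual,
               tolerance = 1e-6 * fit2$ss_total)
  expect_equal(fit2$df_residual, 60 - 4)

  dd$a2 <- dd$a
  expect_error(ols_fit(dd, "ts", c("a", "a2")), "a2")
})

test_that("coefficients of a generating equation are recovered within 3 SE", {
  truth <- reference_model("discovery_st")
  rec <- simulate_calibration_records(truth, n = 1600, target_r2 = 0.9,
                                      seed = 101)
  fit <- ols_fit(rec, "ts", c("x2", "x3_fwhm"))
  est <- tidy(fit)
  expected <- c(90.68, -62.44, 1.05)
  expect_true(all(abs(est$estimate - expected) <= 3 * est$std_error))
})

test_that("the partial F equals the squared t of the entering coefficient", {
  set.seed(23)
  d <- tibble::tibble(x1 = rnorm(200), x2 = rnorm(200))
  d$ts <- 1 + 2 * d$x1 + 0.3 * d$x2 + rnorm(200)
  base <- ols_fit(d, "ts", "x1")
  cand <- ols_fit(d, "ts", c("x1", "x2"))
  pf_res <- partial_f(base, cand)
  t2 <- unname(tidy(cand)$statistic[3]^2)
  expect_equal(pf_res$f_statistic, t2, tolerance = 1e-8)

  expect_error(partial_f(cand, base), "nest")
  d$x1dup <- d$x1
  expect_error(ols_fit(d, "ts", c("x1", "x1dup")), "x1dup")

  # a pure-noise predictor rarely clears the F-to-enter bar
  exceed <- 0L
  for (s in 1:20) {
    set.seed(400 + s)
    dn <- tibble::tibble(x = rnorm(1000), z = rnorm(1000))
    dn$ts <- 2 + dn$x + rnorm(1000)
    f <- partial_f(ols_fit(dn, "ts", "x"),
                   ols_fit(dn, "ts", c("x", "z")))$f_statistic
    if (f > 4) exceed <- exceed + 1L
  }
  expect_lte(exceed, 2L)  # >= 90% of replicates below the bar
})

test_that("forward selection keeps real predictors and drops decoys", {
  set.seed(5)
  d <- tibble::tibble(x1 = rnorm(500), x2 = rnorm(500),
                      flatline = rep(1, 500))
  d$ts <- 2 + 3 * d$x1 + rnorm(500, 0, 0.1)
  model <- stepwise_forward(d, candidates = c("x1", "x2", "flatline"))
  expect_equal(model$selection_order, "x1")
  expect_false("flatline" %in% model$selection_order)  # zero variance never enters

  # selection path agrees with an independent normal-equations oracle
  for (s in 1:10) {
    set.seed(600 + s)
    n <- 300
    dd <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n), e = rnorm(n))
    beta <- sample(c(0, 0, 1.5, -2))
    dd$ts <- as.vector(as.matrix(dd) %*% beta) + rnorm(n)
    got <- stepwise_forward(dd, candidates = c("a", "b", "c", "e"))
    want <- oracle_forward_selection(dd, "ts", c("a", "b", "c", "e"))
    expect_equal(got$selection_order, want)
  }
})

test_that("standardized coefficients rank predictors scale-free", {
  set.seed(8)
  d <- tibble::tibble(u = rnorm(300), v = rnorm(300))
  d$ts <- d$u - 0.5 * d$v + rnorm(300, 0, 0.2)
  dz <- dplyr::mutate(d, dplyr::across(dplyr::everything(),
                                       ~ (.x - mean(.x)) / sd(.x)))
  fitz <- ols_fit(dz, "ts", c("u", "v"))
  bz <- standardized_coeffs(fitz, dz)
  expect_equal(unname(bz), unname(fitz$coefficients[c("u", "v")]),
               tolerance = 1e-10)

  # invariance under affine rescaling of a predictor
  fit <- ols_fit(d, "ts", c("u", "v"))
  b0 <- standardized_coeffs(fit, d)
  d2 <- dplyr::mutate(d, u = 100 * u + 7)
  b1 <- standardized_coeffs(ols_fit(d2, "ts", c("u", "v")), d2)
  expect_equal(unname(b0), unname(b1), tolerance = 1e-8)

  # TBR term dominates for data generated from a shipped equation
  rec <- simulate_calibration_records(reference_model("discovery_st"),
                                      n = 1600, target_r2 = 0.9, seed = 12)
  cal <- stepwise_forward(rec)
  expect_lt(cal$std_beta[["x2"]], 0)
  expect_gt(abs(cal$std_beta[["x2"]]), abs(cal$std_beta[["x3_fwhm"]]))
})

test_that("threshold prediction evaluates the calibration equation", {
  hirez <- reference_model("biograph_hirez")
  p <- predict_ts(hirez, tbr = 12, fwhm = 4)
  expect_equal(p$ts_percent, 39L)
  expect_equal(round(p$ts, 1), 39.4)

  dst <- reference_model("discovery_st")
  expect_equal(predict_ts(dst, tbr = 70, fwhm = 6)$ts, 35.432, tolerance = 1e-3)

  # the contrast term vanishes at TBR = 1
  expect_equal(predict_ts(dst, tbr = 1, fwhm = 6)$ts,
               90.68 + 1.05 * 6, tolerance = 1e-10)

  # monotone decreasing in TBR when the contrast coefficient is negative
  ts_path <- predict_ts(dst, tbr = seq(2, 70, by = 1), fwhm = 6)$ts
  expect_true(all(diff(ts_path) < 0))

  # area-term models demand the area
  expect_error(predict_ts(reference_model("discovery_690"), tbr = 8, fwhm = 6),
               "x1_area")

  # physical clipping to [1, 100] percent
  high <- predict_ts(reference_model("discovery_600"), tbr = 1, fwhm = 11)
  expect_lte(high$ts, 100)
})

test_that("shipped reference models match their published rows", {
  tab <- reference_models()
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$b2_tbr < 0))
  expect_true(all(tab$b3_fwhm > 0, na.rm = TRUE))
  expect_true(all(vapply(tab$model_id, function(id) {
    m <- reference_model(id)
    m$selection_order[1] == "x2"
  }, logical(1))))
  dst <- reference_model("discovery_st")
  expect_equal(unname(dst$coefficients),
               c(90.68, -62.44, 1.05))
  expect_equal(dst$r_squared, 0.91)
  expect_equal(dst$shrinkage, -0.008)
  gtf <- reference_model("gemini_tf")
  expect_equal(unname(gtf$coefficients["x1_area"]), 0.0027)
  expect_false("x3_fwhm" %in% names(gtf$coefficients))
})
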