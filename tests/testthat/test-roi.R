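test_that("background statistics come from circular ROIs off the spheres", {
  truth <- small_truth(8)
  k <- 6  # central slice of an 11-slice volume
  bg <- background_mean(truth, k, roi_centers = small_rois(),
                        truth = small_phantom(8))
  expect_equal(bg$bg_mean, 3)
  expect_equal(bg$bg_sd, 0)
  expect_equal(bg$roi_count, 2L)

  # unbiased under the noise model
  img <- simulate_scan(truth, acquisition_spec(psf_fwhm = 0, esd = 5,
                                               noise_coeff = 1, seed = 2))
  bgn <- background_mean(img, k, roi_centers = small_rois())
  se <- sqrt(3 / 5) / sqrt(bgn$n_pixels)
  expect_lt(abs(bgn$bg_mean - 3), 3 * se)

  expect_error(background_mean(truth, k, roi_centers = rbind(c(90, 0))),
               "outside")
  expect_error(background_mean(truth, k, roi_centers = rbind(c(-25, 12)),
                               truth = small_phantom(8)),
               "intersects sphere")
})

test_that("measured TBR is the encircling-ROI max over the background mean", {
  truth <- small_truth(8)
  bg <- background_mean(truth, 6, roi_centers = small_rois())
  s28 <- small_phantom()$spheres[2, ]

  flat <- build_activity_map(small_phantom(1))
  bgf <- background_mean(flat, 6, roi_centers = small_rois())
  expect_equal(measured_tbr(flat, s28, bgf), 1)

  # unblurred: the max equals the true hot value
  expect_equal(measured_tbr(truth, s28, bg), 8)

  # partial volume pulls the measured ratio below the nominal one
  one10 <- phantom_spec(sphere_spec("s10", c(-25, 0, 0), 10), tbr_nominal = 8)
  t10 <- build_activity_map(one10, dim = c(48, 48, 11))
  b10 <- simulate_scan(t10, acquisition_spec(psf_fwhm = 5, noise_coeff = 0))
  bg10 <- background_mean(b10, 6, roi_centers = small_rois())
  expect_lt(measured_tbr(b10, one10$spheres[1, ], bg10), 8)

  expect_error(measured_tbr(truth, s28, tibble::tibble(bg_mean = 0, bg_sd = 0)),
               "positive")
})

test_that("the detectability rule separates contrast from the noise floor", {
  flat <- build_activity_map(small_phantom(1))
  bgf <- background_mean(flat, 6, roi_centers = small_rois())
  for (s in 1:2) {
    expect_false(detectable(flat, small_phantom(1)$spheres[s, ], bgf))
  }

  # zero background SD: any excess over the mean detects
  truth <- small_truth(8)
  bg0 <- background_mean(truth, 6, roi_centers = small_rois())
  expect_true(detectable(truth, small_phantom()$spheres[1, ], bg0))

  # strong contrast over realistic noise
  hot <- build_activity_map(small_phantom(70))
  img <- simulate_scan(hot, acquisition_spec(psf_fwhm = 6.3, esd = 2,
                                             noise_coeff = 0.25, seed = 9))
  bgn <- background_mean(img, 6, roi_centers = small_rois())
  expect_true(detectable(img, small_phantom()$spheres[2, ], bgn))
})

test_that("autocontouring recovers step-edge disks and nests in the threshold", {
  disk <- make_disk_volume(22, fwhm = 0, bg = 1, hot = 10)
  n_disk <- sum(disk$data == 10)
  for (ts in c(15, 50, 99)) {
    res <- autocontour_area(disk, ts, center = c(0, 0), window_mm = 40,
                            slice_index = 1)
    expect_equal(res$area_mm2, n_disk * 1)
  }
  res100 <- autocontour_area(disk, 100, center = c(0, 0), window_mm = 40,
                             slice_index = 1)
  expect_gte(res100$n_pixels, 1)
  expect_equal(res100$area_mm2, n_disk * 1)  # step edge: all disk pixels at max

  # superlevel-set nesting: area nonincreasing in the threshold
  blurred <- make_disk_volume(22, fwhm = 8, bg = 1, hot = 10)
  noisy <- blurred
  set.seed(31)
  noisy$data <- noisy$data + rnorm(length(noisy$data), 0, 0.05)
  areas <- vapply(1:100, function(ts) {
    autocontour_area(noisy, ts, center = c(0, 0), window_mm = 46,
                     slice_index = 1)$area_mm2
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("the threshold search matches known areas and honours tolerance", {
  disk <- make_disk_volume(22, fwhm = 0, bg = 1, hot = 10)
  sp <- disk_sphere_row(22)
  res <- find_optimal_ts(disk, sp)
  expect_true(res$converged)
  expect_lt(abs(res$measured_area - 380.13), 4)  # pixelisation only
  # area is flat in the threshold above the step; ties go to the largest
  expect_equal(res$ts_percent, 100)

  # degenerate tolerance: converged only on an exact pixel-area match
  res0 <- find_optimal_ts(disk, sp, tolerance = 0)
  expect_false(res0$converged)

  # agreement with the numerical-convolution boundary oracle
  for (case in list(c(13, 6), c(37, 11))) {
    vol <- make_disk_volume(case[1], case[2], pixel = 0.5)
    found <- find_optimal_ts(vol, disk_sphere_row(case[1]),
                             margin_mm = case[2] / 2 + 2)
    expect_lt(abs(found$ts_percent - oracle_ts_percent(case[1], case[2])), 2)
  }
})

test_that("record building keeps detectable spheres and counts the rest", {
  grid <- generate_experiment_grid(
    small_phantom(), tbrs = c(8, 25), esds = c(2, 5),
    recons = list(recon_spec(6), recon_spec(9)),
    dim = c(48, 48, 11), psf_fwhm = 6.3, noise_coeff = 0.25, master_seed = 3
  )
  rec <- build_records(grid, roi_centers = small_rois())
  expect_equal(nrow(rec) + attr(rec, "skipped"), length(grid) * 2)
  expect_true(all(rec$ts >= 1 & rec$ts <= 100))
  expect_equal(rec$x2, 1 - 1 / rec$tbr_measured, tolerance = 1e-9)
  expect_true(all(rec$x2 >= 0 & rec$x2 < 1))
  expect_setequal(unique(rec$x3_fwhm), c(6, 9))

  # contrast-free grid yields no records at all
  flat_grid <- generate_experiment_grid(
    small_phantom(1), tbrs = 1, esds = 3, recons = list(recon_spec(6)),
    dim = c(48, 48, 11), psf_fwhm = 0, noise_coeff = 0
  )
  rec0 <- build_records(flat_grid, roi_centers = small_rois())
  expect_equal(nrow(rec0), 0)
  expect_equal(attr(rec0, "skipped"), 2L)
})
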