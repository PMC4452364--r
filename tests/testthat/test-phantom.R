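test_that("activity map places hot spheres in a warm background", {
  # contrast-free case: TBR 1 gives a uniform volume at the background value
  flat <- build_activity_map(iec_phantom(tbr_nominal = 1))
  expect_true(all(flat$data == 3))

  truth <- build_activity_map(iec_phantom(tbr_nominal = 8))
  expect_setequal(unique(as.vector(truth$data)), c(3, 24))
  expect_equal(max(truth$data), 24)  # 8 x 3 kBq/mL

  # voxel-centre rasterisation recovers the analytic sphere volume
  one <- phantom_spec(sphere_spec("s37", c(0, 0, 0), 37), tbr_nominal = 8)
  vol <- build_activity_map(one, dim = c(45, 45, 45), voxel = c(1, 1, 1))
  v_ml <- sum(vol$data == 24) * 1 / 1000
  expect_lt(abs(v_ml - 4 / 3 * pi * 18.5^3 / 1000) / (4 / 3 * pi * 18.5^3 / 1000),
            0.02)
})

test_that("impossible phantom geometry is rejected with the sphere named", {
  big <- phantom_spec(sphere_spec("s37", c(100, 0, 0), 37), tbr_nominal = 8)
  expect_error(build_activity_map(big, dim = c(40, 40, 40), voxel = c(1, 1, 1)),
               "s37")
  overlapping <- dplyr::bind_rows(sphere_spec("a", c(0, 0, 0), 22),
                                  sphere_spec("b", c(10, 0, 0), 22))
  expect_error(phantom_spec(overlapping), "overlap")
})

test_that("scan simulation degrades the truth as specified", {
  truth <- small_truth(8)
  # identity when there is neither blur nor noise
  same <- simulate_scan(truth, acquisition_spec(psf_fwhm = 0, noise_coeff = 0))
  expect_identical(same$data, truth$data)

  # noise is zero-mean: background mean within 3 SE of 3 kBq/mL
  flat <- image_volume(array(3, c(30, 30, 12)), voxel = c(2.7, 2.7, 3.3))
  n <- length(flat$data)
  expect_gt(n, 1e4)
  noisy <- simulate_scan(flat, acquisition_spec(psf_fwhm = 0, esd = 5,
                                                noise_coeff = 1, seed = 11))
  se <- sqrt(3 / 5) / sqrt(n)
  expect_lt(abs(mean(noisy$data) - 3), 3 * se)

  # noise SD scales as 1/sqrt(ESD)
  sd2 <- sd(simulate_scan(flat, acquisition_spec(0, esd = 2, noise_coeff = 1,
                                                 seed = 3))$data - 3)
  sd5 <- sd(simulate_scan(flat, acquisition_spec(0, esd = 5, noise_coeff = 1,
                                                 seed = 4))$data - 3)
  expect_lt(abs(sd2 / sd5 - sqrt(5 / 2)) / sqrt(5 / 2), 0.10)
})

test_that("noiseless simulation is linear and seeded runs reproduce", {
  truth <- small_truth(8)
  acq <- acquisition_spec(psf_fwhm = 5, noise_coeff = 0)
  a <- simulate_scan(truth, acq)
  truth2 <- truth; truth2$data <- 2 * truth$data
  b <- simulate_scan(truth2, acq)
  expect_equal(b$data, 2 * a$data, tolerance = 1e-12)

  noisy_acq <- acquisition_spec(psf_fwhm = 5, esd = 3, noise_coeff = 0.25,
                                seed = 42)
  expect_identical(simulate_scan(truth, noisy_acq)$data,
                   simulate_scan(truth, noisy_acq)$data)
})

test_that("blur attenuates the peak of spheres below the resolution limit", {
  one <- phantom_spec(sphere_spec("s10", c(0, 0, 0), 10), tbr_nominal = 8)
  truth <- build_activity_map(one, dim = c(32, 32, 16))
  img <- simulate_scan(truth, acquisition_spec(psf_fwhm = 6.3, noise_coeff = 0))
  expect_lt(max(img$data), 24)
})

test_that("transaxial filter has the stated width and conserves intensity", {
  # fwhm = 0 is the identity
  truth <- small_truth(8)
  expect_identical(apply_transaxial_filter(truth, recon_spec(0))$data,
                   truth$data)

  # impulse response width matches the requested FWHM within half a voxel
  imp <- image_volume(array(0, c(81, 81, 1)), voxel = c(1, 1, 1))
  imp$data[41, 41, 1] <- 1
  out <- apply_transaxial_filter(imp, recon_spec(8))
  prof <- out$data[, 41, 1]
  half <- max(prof) / 2
  above <- which(prof >= half)
  lo <- min(above); hi <- max(above)
  # linear interpolation of the half-max crossings
  f_lo <- lo - 1 + (prof[lo - 1] - half) / (prof[lo - 1] - prof[lo])
  f_hi <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  expect_lt(abs((f_hi - f_lo) - 8), 0.5)

  # per-slice intensity conservation under heavy smoothing
  sm <- apply_transaxial_filter(truth, recon_spec(11))
  for (k in c(1, 6, 11)) {
    s0 <- sum(truth$data[, , k]); s1 <- sum(sm$data[, , k])
    expect_lt(abs(s1 - s0) / s0, 1e-3)
  }
})

test_that("the experiment grid enumerates the acquisition protocol", {
  expect_equal(default_tbr_grid(), c(2.5, 4, 8, 16, 25, 35, 47, 55, 70))

  ph <- iec_phantom()
  grid <- generate_experiment_grid(ph, tbrs = default_tbr_grid(),
                                   esds = c(2, 3, 4, 5),
                                   recons = list(recon_spec(9)),
                                   dim = c(96, 96, 20), psf_fwhm = 0,
                                   noise_coeff = 0, master_seed = 5)
  expect_length(grid, 36)
  expect_equal(length(grid) * nrow(ph$spheres), 324)

  tiny <- generate_experiment_grid(ph, tbrs = 8, esds = 3,
                                   recons = list(recon_spec(9)),
                                   dim = c(96, 96, 20), psf_fwhm = 0,
                                   noise_coeff = 0)
  expect_length(tiny, 1)
  expect_length(generate_experiment_grid(ph, tbrs = numeric(), esds = 3,
                                         recons = list(recon_spec(9))), 0)

  # seed policy: regenerating the same grid reproduces the volumes
  grid2 <- generate_experiment_grid(ph, tbrs = c(8, 16), esds = 3,
                                    recons = list(recon_spec(9)),
                                    dim = c(96, 96, 20), master_seed = 7)
  grid3 <- generate_experiment_grid(ph, tbrs = c(8, 16), esds = 3,
                                    recons = list(recon_spec(9)),
                                    dim = c(96, 96, 20), master_seed = 7)
  expect_identical(grid2[[2]]$volume$data, grid3[[2]]$volume$data)
  expect_identical(grid2[[1]]$meta$seed, grid3[[1]]$meta$seed)
})
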