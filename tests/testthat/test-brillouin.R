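test_that("theoretical shift follows 2 n v / lambda", {
  # water at 660 nm: 2 * 1.33 * 1482 / 660 GHz
  expect_equal(theoretical_shift(1.33, 1482, 660), 2 * 1.33 * 1482 / 660)
  expect_equal(theoretical_shift(1.33, 1482, 660), 5.973, tolerance = 1e-4)
  expect_identical(theoretical_shift(1.33, 0, 660), 0)
  # linear in n and v, inverse in lambda
  expect_equal(theoretical_shift(2 * 1.33, 1482, 660),
               2 * theoretical_shift(1.33, 1482, 660))
  expect_equal(theoretical_shift(1.33, 3 * 1482, 660),
               3 * theoretical_shift(1.33, 1482, 660))
  expect_equal(theoretical_shift(1.33, 1482, 2 * 660),
               theoretical_shift(1.33, 1482, 660) / 2)
  expect_error(theoretical_shift(-1, 1482, 660), "positive")
})

test_that("Lorentzian peak fitting finds centers to sub-pixel precision and is baseline invariant", {
  cfg <- brillouin_sim_config(true_shift = 5, noise_model = "none")
  sp <- simulate_brillouin_spectrum(cfg)
  pk <- fit_spectral_peaks(sp, n_peaks = 4)
  expect_equal(pk$center_px, sp$metadata$peak_positions, tolerance = 0.1)
  expect_equal(pk$fwhm_px, rep(cfg$linewidth / cfg$dispersion, 4),
               tolerance = 0.05)

  # constant offset leaves the centers unchanged
  sp_off <- sp
  sp_off$intensity <- sp$intensity + 500
  pk_off <- fit_spectral_peaks(sp_off, n_peaks = 4)
  expect_equal(pk_off$center_px, pk$center_px, tolerance = 1e-3)

  # flat spectrum: no peaks found
  flat <- simulate_brillouin_spectrum(
    brillouin_sim_config(amplitude = 0, noise_model = "none"))
  expect_error(fit_spectral_peaks(flat, n_peaks = 4), "peak")
})

test_that("separation-domain calibration recovers dispersion and FSR", {
  mats <- reference_materials()
  cfg <- brillouin_sim_config(noise_model = "none")
  cal <- brillouin_calibrate(simulate_calibration_set(mats, cfg))
  expect_equal(cal$dispersion, 0.1, tolerance = 0.001 / 0.1)
  expect_equal(cal$free_spectral_range, 30, tolerance = 0.1 / 30)
  expect_lt(cal$rms_residual_ghz, 1e-3)
  expect_false(cal$quality_warning)
  expect_identical(nrow(tidy(cal)), 3L)

  # exactly two materials: determined 2x2 system, zero residuals
  cal2 <- brillouin_calibrate(simulate_calibration_set(mats[1:2, ], cfg))
  expect_equal(cal2$materials$residual_ghz, c(0, 0), tolerance = 1e-9)
  expect_equal(cal2$dispersion, 0.1, tolerance = 1e-6)

  # one material is insufficient; duplicate shifts are degenerate
  one <- simulate_calibration_set(mats, cfg)[1]
  expect_error(brillouin_calibrate(one), "at least 2")
  two <- simulate_calibration_set(mats[1:2, ], cfg)
  expect_error(brillouin_calibrate(two, known_shifts = c(5, 5)), "degenerate")
})

test_that("round trip generator -> calibrate -> decode recovers the shift over a parameter sweep", {
  mats <- reference_materials()
  for (disp in c(0.05, 0.1)) {
    n_px <- as.integer(2 * (30 / disp + 30 / (2 * disp)))
    cfg <- brillouin_sim_config(noise_model = "none", dispersion = disp,
                                n_pixels = n_px)
    cal <- brillouin_calibrate(simulate_calibration_set(mats, cfg))
    for (omega in c(4.2, 5.97, 7.5)) {
      cfg_s <- brillouin_sim_config(true_shift = omega, dispersion = disp,
                                    n_pixels = n_px, noise_model = "none")
      got <- brillouin_shift(simulate_brillouin_spectrum(cfg_s), cal)
      expect_lt(abs(got$shift_ghz - omega), 1e-3 * 30)
    }
  }
})

test_that("recovered shift increases strictly with the generated shift", {
  mats <- reference_materials()
  cfg <- brillouin_sim_config(noise_model = "none")
  cal <- brillouin_calibrate(simulate_calibration_set(mats, cfg))
  shifts <- purrr::map_dbl(seq(4, 8, by = 0.5), function(om) {
    brillouin_shift(simulate_brillouin_spectrum(
      brillouin_sim_config(true_shift = om, noise_model = "none")), cal)$shift_ghz
  })
  expect_true(all(diff(shifts) > 0))
})

test_that("decoding flags order ambiguity at the FSR/2 boundary", {
  mats <- reference_materials()
  cfg <- brillouin_sim_config(noise_model = "none")
  cal <- brillouin_calibrate(simulate_calibration_set(mats, cfg))
  # a spectrum whose intra-order separation decodes to ~0 GHz separation
  # (shift at FSR/2) cannot be resolved into four peaks; near-boundary
  # synthetic cases instead collapse the pair and must error
  near <- simulate_brillouin_spectrum(
    brillouin_sim_config(true_shift = 14.9, noise_model = "none"))
  expect_error(brillouin_shift(near, cal))
})

test_that("shift maps summarize ROIs and flag invalid points", {
  mats <- reference_materials()
  cfg <- brillouin_sim_config(noise_model = "none")
  cal <- brillouin_calibrate(simulate_calibration_set(mats, cfg))
  mk <- function(om) simulate_brillouin_spectrum(
    brillouin_sim_config(true_shift = om, noise_model = "none"))

  # constant field: ROI mean is the constant, SD 0
  grid <- matrix(list(), 3, 3)
  for (i in 1:9) grid[[i]] <- mk(5.5)
  bm <- map_shifts(grid, cal)
  expect_equal(bm$roi_mean_ghz, 5.5, tolerance = 1e-3)
  expect_equal(bm$roi_sd_ghz, 0, tolerance = 1e-6)
  expect_identical(bm$invalid_fraction, 0)

  # two-region phantom: ROI restricted to the inner points returns omega1
  grid2 <- matrix(list(), 3, 3)
  for (i in 1:9) grid2[[i]] <- mk(5.0)
  grid2[[5]] <- mk(6.5)
  roi <- matrix(FALSE, 3, 3)
  roi[2, 2] <- TRUE
  bm2 <- map_shifts(grid2, cal, roi = roi)
  expect_equal(bm2$roi_mean_ghz, 6.5, tolerance = 1e-3)

  # dead grid points are flagged; an all-dead ROI errors
  flat <- simulate_brillouin_spectrum(
    brillouin_sim_config(amplitude = 0, noise_model = "none"))
  grid3 <- grid2
  grid3[[1]] <- flat
  bm3 <- map_shifts(grid3, cal)
  expect_false(bm3$valid[1, 1])
  expect_gt(bm3$invalid_fraction, 0)
  grid4 <- matrix(list(flat, flat, flat, flat), 2, 2)
  expect_error(map_shifts(grid4, cal), "no valid")
})
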