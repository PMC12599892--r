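test_that("phase-displacement conversion matches the closed form and inverts the forward model", {
  # dphi = pi at 1310 nm, n = 1.38 -> u = 1310 / (4 * 1.38) nm
  vals <- matrix(0, 8, 8)
  vals[3, 4] <- pi
  m <- st_map(vals, kind = "phase", axial_pitch = 5, frame_interval = 1e-5,
              center_wavelength = 1310, refractive_index = 1.38)
  u <- phase_to_displacement(m)
  expect_equal(u$values[3, 4], 1310 / (4 * 1.38), tolerance = 1e-12)
  expect_equal(sum(u$values != 0), 1L)
  expect_identical(u$kind, "displacement")

  # zero phase -> zero displacement
  z <- st_map(matrix(0, 8, 8), kind = "phase", axial_pitch = 5,
              frame_interval = 1e-5)
  expect_true(all(phase_to_displacement(z)$values == 0))

  # round trip through the generator (no wrapping, no noise) is exact
  cfg <- fast_oce_config(phase_noise_std = 0)
  map <- simulate_oce_map(cfg)
  u2 <- phase_to_displacement(map)
  z_m <- map_depths(map) * 1e-6
  expected <- cfg$displacement_amplitude * exp(
    -outer(cfg$pulse_center_time + z_m / cfg$true_speed, map_times(map),
           function(a, t) (t - a)^2) / (2 * cfg$pulse_width^2))
  expect_equal(u2$values, expected, tolerance = 1e-10)

  # kind and configuration errors
  expect_error(phase_to_displacement(u), "phase")
  m_bad <- m
  m_bad$center_wavelength <- NA_real_
  expect_error(phase_to_displacement(m_bad), "refractive")
})

test_that("temporal unwrapping recovers displacements whose phase exceeds pi", {
  cfg <- fast_oce_config(displacement_amplitude = 300, phase_noise_std = 0)
  map <- simulate_oce_map(cfg, allow_wrapping = TRUE)
  u <- phase_to_displacement(map, unwrap = TRUE)
  expect_gt(u$metadata$wrap_events, 0)
  expect_equal(max(u$values), 300, tolerance = 1e-6)
})

test_that("delay estimation recovers time-of-flight differences and flags bad depths", {
  cfg <- fast_oce_config(true_speed = 2, phase_noise_std = 0)
  u <- phase_to_displacement(simulate_oce_map(cfg))
  prof <- estimate_delays(u, exclude_surface = 0)
  # depths 100 um apart differ in delay by 100e-6 / 2 = 50 us
  i1 <- which.min(abs(prof$depth_um - 100))
  i0 <- which.min(abs(prof$depth_um - 0))
  expect_lt(abs(prof$delay_s[i1] - prof$delay_s[i0] - 50e-6),
            cfg$frame_interval / 2)
  # sub-sample lags cost a little correlation, but the pulse dominates
  expect_true(all(prof$quality > 0.95))

  # a time-shifted copy of one waveform gives a constant delay k * dt
  k <- 7L
  ref <- u$values[1, ]
  shifted <- c(rep(ref[1], k), ref[seq_len(length(ref) - k)])
  vals <- rbind(matrix(rep(ref, each = 4), nrow = 4, byrow = FALSE),
                matrix(rep(shifted, each = 4), nrow = 4, byrow = FALSE))
  m <- st_map(vals, kind = "displacement", axial_pitch = cfg$depth_extent / 8,
              frame_interval = cfg$frame_interval)
  p <- estimate_delays(m, exclude_surface = 0)
  # edge padding of the shifted copy perturbs the peak slightly
  expect_lt(max(abs(p$delay_s[5:8] - k * cfg$frame_interval)),
            0.2 * cfg$frame_interval)

  # flat waveforms are flagged, not fatal
  vals2 <- vals
  vals2[8, ] <- 3.14
  p2 <- estimate_delays(st_map(vals2, kind = "displacement",
                               axial_pitch = 50, frame_interval = 1e-5),
                        exclude_surface = 0)
  expect_true(is.na(p2$delay_s[8]))
  expect_identical(p2$quality[8], 0)

  # pure noise: every depth has low correlation quality
  set.seed(4)
  noise <- matrix(rnorm(32 * 128), 32, 128)
  pn <- estimate_delays(st_map(noise, kind = "displacement", axial_pitch = 10,
                               frame_interval = 1e-5), exclude_surface = 0)
  expect_true(all(pn$quality[-1] < 0.5))
})

test_that("delay estimation is antisymmetric under reference swap", {
  cfg <- fast_oce_config(true_speed = 1, seed = 21)
  u <- phase_to_displacement(simulate_oce_map(cfg))
  d <- map_depths(u)
  pA <- estimate_delays(u, reference_depth = d[5], exclude_surface = 0)
  pB <- estimate_delays(u, reference_depth = d[25], exclude_surface = 0)
  tau_AB <- pA$delay_s[25]
  tau_BA <- pB$delay_s[5]
  expect_equal(tau_AB, -tau_BA, tolerance = cfg$frame_interval / 4)
})

test_that("wave-speed fitting matches the normal-equations oracle and rejects degenerate profiles", {
  # exact line tau = z / c, c = 2
  z <- seq(0, 350, by = 25)
  prof <- structure(
    tibble::tibble(depth_um = z, delay_s = z * 1e-6 / 2,
                   quality = rep(1, length(z))),
    class = c("delay_profile", class(tibble::tibble())))
  fit <- fit_wave_speed(prof)
  expect_equal(fit$wave_speed_mps, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # OLS slope equals the closed-form normal-equations slope on noisy data
  set.seed(8)
  prof$delay_s <- z * 1e-6 / 2 + rnorm(length(z), sd = 3e-6)
  fit2 <- fit_wave_speed(prof)
  b_oracle <- normal_eq_slope(z * 1e-6, prof$delay_s)
  expect_equal(1 / fit2$wave_speed_mps, b_oracle, tolerance = 1e-10)

  # Theil-Sen agrees on clean data and survives one outlier depth
  prof_ts <- prof
  prof_ts$delay_s <- z * 1e-6 / 2
  prof_ts$delay_s[5] <- 1e-3
  fit_ts <- fit_wave_speed(prof_ts, method = "theil_sen")
  expect_equal(fit_ts$wave_speed_mps, 2, tolerance = 0.01)

  # degenerate cases
  prof$delay_s <- rep(1e-5, length(z))
  expect_error(fit_wave_speed(prof), "no propagating wave")
  prof$quality <- rep(0, length(z))
  expect_error(fit_wave_speed(prof), "insufficient")
})

test_that("Young's modulus follows E = 2 rho (1 + nu) c^2", {
  expect_identical(young_modulus(1), 2980)
  expect_identical(young_modulus(0), 0)
  # homogeneity of degree 2 for any parameters
  for (c0 in c(0.3, 1.7, 4)) {
    expect_equal(young_modulus(2 * c0, density = 1200, poisson_ratio = 0.3),
                 4 * young_modulus(c0, density = 1200, poisson_ratio = 0.3))
  }
  # E / c^2 is the constant 2 rho (1 + nu)
  cs <- c(0.5, 1, 2, 4)
  expect_equal(young_modulus(cs) / cs^2, rep(2980, 4))
  expect_error(young_modulus(-1), "non-negative")
  expect_error(young_modulus(1, poisson_ratio = 0.5), "below 0.5")
})

test_that("triplicate analysis aggregates replicates and tolerates partial failure", {
  mk <- function(seed) simulate_oce_map(fast_oce_config(seed = seed))
  res <- analyze_oce_measurement(list(mk(1), mk(2), mk(3)))
  expect_s3_class(res, "elasticity_result")
  expect_identical(res$n_replicates_used, 3L)
  expect_equal(res$wave_speed_mps, mean(tidy(res)$wave_speed_mps))
  expect_equal(res$young_modulus_pa, 2980 * res$wave_speed_mps^2)
  expect_equal(glance(res)$speed_sd_mps, sd(tidy(res)$wave_speed_mps))

  # identical noiseless replicates: SD 0
  m0 <- simulate_oce_map(fast_oce_config(phase_noise_std = 0))
  r0 <- analyze_oce_measurement(list(m0, m0, m0))
  expect_equal(r0$speed_sd_mps, 0)
  expect_equal(r0$wave_speed_mps, 2, tolerance = 0.01)

  # one dead replicate is dropped with a warning; all dead is fatal
  dead <- st_map(matrix(rnorm(32 * 128, sd = 1e-3), 32, 128),
                 kind = "displacement", axial_pitch = 12.5,
                 frame_interval = 1e-5)
  expect_warning(r2 <- analyze_oce_measurement(list(mk(4), mk(5), dead)),
                 "failed")
  expect_identical(r2$n_replicates_used, 2L)
  expect_error(suppressWarnings(analyze_oce_measurement(list(dead))), "all replicates failed")
})

test_that("noiseless parameter recovery is within 1% across the speed grid", {
  for (c0 in c(0.5, 1, 2, 4)) {
    cfg <- oce_sim_config(true_speed = c0, phase_noise_std = 0)
    fit <- fit_wave_speed(estimate_delays(
      phase_to_displacement(simulate_oce_map(cfg))))
    expect_lt(abs(fit$wave_speed_mps - c0) / c0, 0.01)
  }
})
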