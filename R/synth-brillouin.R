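#' Configuration for the synthetic VIPA Brillouin spectrum
#'
#' Emulates a two-stage VIPA spectrometer readout: exactly two spectral
#' orders on the camera axis, each containing an anti-Stokes and a Stokes
#' Lorentzian peak. Within one order the two peaks are separated by
#' `(FSR - 2 * shift) / dispersion` pixels -- the convention the
#' calibration and decoding in [brillouin_calibrate()] and
#' [brillouin_shift()] rely on. Order centers sit at
#' `(n_pixels + 1) / 2 -/+ FSR / (2 * dispersion)`.
#'
#' @param true_shift Ground-truth Brillouin shift in GHz; must satisfy
#'   `0 < true_shift < free_spectral_range / 2`.
#' @param linewidth Lorentzian FWHM in GHz.
#' @param free_spectral_range VIPA free spectral range in GHz (~30 GHz for
#'   the emulated instrument).
#' @param dispersion Spectral dispersion in GHz per pixel.
#' @param n_pixels Number of camera pixels (>= 64).
#' @param amplitude Peak amplitude in counts.
#' @param baseline Constant background in counts.
#' @param noise_model One of `"none"`, `"gaussian"`, `"poisson"`.
#' @param noise_sd Gaussian noise sigma in counts (used only by the
#'   gaussian model; the poisson model takes its variance from the signal).
#' @param seed RNG seed or NULL.
#' @return A list of class `brillouin_sim_config`.
#' @examples
#' cfg <- brillouin_sim_config(true_shift = 5.2)
#' sp <- simulate_brillouin_spectrum(cfg)
#' @export
brillouin_sim_config <- function(true_shift = 5.2,
                                 linewidth = 0.6,
                                 free_spectral_range = 30,
                                 dispersion = 0.1,
                                 n_pixels = 640L,
                                 amplitude = 1000,
                                 baseline = 50,
                                 noise_model = c("none", "gaussian", "poisson"),
                                 noise_sd = 5,
                                 seed = NULL) {
  noise_model <- match.arg(noise_model)
  check_scalar(free_spectral_range, "free_spectral_range", lower = 0,
               strict_lower = TRUE)
  check_scalar(true_shift, "true_shift", lower = 0,
               upper = free_spectral_range / 2, strict_lower = TRUE)
  if (true_shift >= free_spectral_range / 2) {
    abort("`true_shift` must be below half the free spectral range.")
  }
  check_scalar(linewidth, "linewidth", lower = 0, strict_lower = TRUE)
  check_scalar(dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  check_scalar(n_pixels, "n_pixels", lower = 64)
  check_scalar(amplitude, "amplitude", lower = 0)
  check_scalar(baseline, "baseline", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  structure(
    list(true_shift = true_shift, linewidth = linewidth,
         free_spectral_range = free_spectral_range, dispersion = dispersion,
         n_pixels = as.integer(n_pixels), amplitude = amplitude,
         baseline = baseline, noise_model = noise_model,
         noise_sd = noise_sd, seed = seed),
    class = "brillouin_sim_config"
  )
}

# Lorentzian with unit peak height, FWHM w, evaluated at x around center c.
lorentzian <- function(x, center, fwhm) {
  hw2 <- (fwhm / 2)^2
  hw2 / ((x - center)^2 + hw2)
}

# Peak pixel positions for the two simulated orders under the
# (FSR - 2 * shift) intra-order separation convention.
vipa_peak_positions <- function(shift, fsr, dispersion, n_pixels) {
  mid <- (n_pixels + 1) / 2
  order_centers <- mid + c(-1, 1) * fsr / (2 * dispersion)
  half_sep <- (fsr / 2 - shift) / dispersion
  list(order_centers = order_centers,
       peaks = sort(c(order_centers[1] + c(-1, 1) * half_sep,
                      order_centers[2] + c(-1, 1) * half_sep)))
}

#' Simulate a two-order VIPA Brillouin spectrum
#'
#' @param config A [brillouin_sim_config()].
#' @return A [brillouin_spectrum()] whose metadata records the ground-truth
#'   shift, dispersion, FSR and peak positions.
#' @export
simulate_brillouin_spectrum <- function(config) {
  stopifnot(inherits(config, "brillouin_sim_config"))
  geom <- vipa_peak_positions(config$true_shift, config$free_spectral_range,
                              config$dispersion, config$n_pixels)
  which_order <- rep(1:2, each = 2)
  outside <- geom$peaks < 1 | geom$peaks > config$n_pixels
  if (any(outside)) {
    abort(sprintf(
      "peak(s) of spectral order %s fall outside the %d-pixel axis (positions %s); widen the axis or change dispersion.",
      paste(unique(which_order[outside]), collapse = ", "), config$n_pixels,
      paste(sprintf("%.1f", geom$peaks[outside]), collapse = ", ")))
  }
  px <- seq_len(config$n_pixels)
  fwhm_px <- config$linewidth / config$dispersion
  signal <- config$baseline
  for (p in geom$peaks) {
    signal <- signal + config$amplitude * lorentzian(px, p, fwhm_px)
  }
  local_seed(config$seed)
  intensity <- switch(
    config$noise_model,
    none = signal,
    gaussian = pmax(0, signal + rnorm(length(signal), sd = config$noise_sd)),
    poisson = rpois(length(signal), lambda = signal)
  )
  brillouin_spectrum(
    intensity, exposure = 0.1,
    metadata = list(true_shift = config$true_shift,
                    dispersion = config$dispersion,
                    free_spectral_range = config$free_spectral_range,
                    linewidth = config$linewidth,
                    order_centers = geom$order_centers,
                    peak_positions = geom$peaks,
                    noise_model = config$noise_model, seed = config$seed)
  )
}

#' Reference liquids for spectrometer calibration
#'
#' Literature refractive indices and acoustic velocities for the standard
#' calibration liquids (water, acetone, methanol) and their backscattering
#' Brillouin shifts `2 n v / lambda` at the given wavelength. These serve
#' as the known shifts fed to [simulate_calibration_set()] and
#' [brillouin_calibrate()]; on a real instrument they are user inputs.
#'
#' @param wavelength Optical wavelength in nm (default 660).
#' @return A tibble with columns `material`, `refractive_index`,
#'   `acoustic_velocity_mps`, `shift_ghz`.
#' @examples
#' reference_materials()
#' @export
reference_materials <- function(wavelength = 660) {
  mat <- tibble(
    material = c("water", "acetone", "methanol"),
    refractive_index = c(1.330, 1.357, 1.328),
    acoustic_velocity_mps = c(1482, 1174, 1103)
  )
  mat$shift_ghz <- theoretical_shift(mat$refractive_index,
                                     mat$acoustic_velocity_mps, wavelength)
  mat
}

#' Simulate a spectrometer calibration set
#'
#' One spectrum per reference material, all sharing the instrument geometry
#' (dispersion, FSR, pixel axis) of `config`, each tagged with its known
#' shift in the metadata and label.
#'
#' @param materials Data frame with columns `material` (or `name`) and
#'   `shift_ghz`, e.g. from [reference_materials()]. At least two materials
#'   with distinct shifts.
#' @param config A [brillouin_sim_config()]; its `true_shift` is ignored
#'   and replaced per material.
#' @return A list of [brillouin_spectrum()] objects.
#' @export
simulate_calibration_set <- function(materials, config) {
  stopifnot(inherits(config, "brillouin_sim_config"))
  materials <- as_tibble(materials)
  if (!"material" %in% names(materials) && "name" %in% names(materials)) {
    materials$material <- materials$name
  }
  if (!all(c("material", "shift_ghz") %in% names(materials))) {
    abort("`materials` needs columns `material` and `shift_ghz`.")
  }
  if (nrow(materials) < 2L) {
    abort("calibration needs at least 2 reference materials.")
  }
  if (anyDuplicated(materials$shift_ghz)) {
    abort("duplicate reference shifts make the calibration degenerate.")
  }
  purrr::pmap(list(materials$material, materials$shift_ghz,
                   seq_len(nrow(materials))),
              function(name, shift, i) {
    cfg_i <- config
    cfg_i$true_shift <- shift
    if (!is.null(config$seed)) cfg_i$seed <- config$seed + i
    sp <- simulate_brillouin_spectrum(cfg_i)
    sp$label <- name
    sp$metadata$known_shift <- shift
    sp
  })
}
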