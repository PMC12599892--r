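#' Configuration for the synthetic elastography forward model
#'
#' Defines a phase-sensitive OCE acquisition of a mechanical wave crossing a
#' spheroid-sized sample at a known speed. The forward model launches a
#' Gaussian displacement pulse that arrives at depth `z` at
#' `pulse_center_time + z / true_speed`, converts displacement to optical
#' phase via `dphi = 4 pi n u / lambda0`, adds Gaussian phase noise and
#' wraps to (-pi, pi].
#'
#' The default phase noise standard deviation is calibrated so that the
#' equivalent displacement noise is 2.6 nm, the displacement stability of
#' the swept-source system this emulates.
#'
#' @param true_speed Ground-truth wave speed in m/s (> 0).
#' @param depth_extent Imaged depth range in um (~400 um spheroid).
#' @param n_depth Number of axial samples.
#' @param frame_interval Time between frames in s.
#' @param n_frames Number of frames.
#' @param pulse_center_time Arrival time of the pulse at depth 0, in s.
#' @param pulse_width Gaussian temporal sigma of the pulse, in s.
#' @param displacement_amplitude Peak axial displacement in nm.
#' @param refractive_index Tissue refractive index (soft-tissue convention
#'   1.38; the phase-displacement conversion needs it).
#' @param center_wavelength Source center wavelength in nm.
#' @param phase_noise_std Additive Gaussian phase noise sigma in rad.
#'   Default `4 pi * refractive_index * 2.6 / center_wavelength` (2.6 nm
#'   displacement stability).
#' @param seed RNG seed for the noise draw, or NULL.
#'
#' @return A list of class `oce_sim_config`.
#' @examples
#' cfg <- oce_sim_config(true_speed = 2)
#' map <- simulate_oce_map(cfg)
#' @export
oce_sim_config <- function(true_speed = 2,
                           depth_extent = 400,
                           n_depth = 64L,
                           frame_interval = 5e-6,
                           n_frames = 256L,
                           pulse_center_time = 1e-4,
                           pulse_width = 2.5e-5,
                           displacement_amplitude = 100,
                           refractive_index = 1.38,
                           center_wavelength = 1310,
                           phase_noise_std = NULL,
                           seed = NULL) {
  check_scalar(true_speed, "true_speed", lower = 0, strict_lower = TRUE)
  check_scalar(depth_extent, "depth_extent", lower = 0, strict_lower = TRUE)
  check_scalar(n_depth, "n_depth", lower = 8)
  check_scalar(frame_interval, "frame_interval", lower = 0, strict_lower = TRUE)
  check_scalar(n_frames, "n_frames", lower = 8)
  check_scalar(pulse_width, "pulse_width", lower = 0, strict_lower = TRUE)
  check_scalar(displacement_amplitude, "displacement_amplitude", lower = 0)
  check_scalar(refractive_index, "refractive_index", lower = 1)
  check_scalar(center_wavelength, "center_wavelength", lower = 0,
               strict_lower = TRUE)
  phase_noise_std <- phase_noise_std %||%
    (4 * pi * refractive_index * 2.6 / center_wavelength)
  check_scalar(phase_noise_std, "phase_noise_std", lower = 0)
  # the pulse (out to 3 sigma) must arrive at the deepest sample inside the
  # acquisition window, otherwise the delay-slope fit has nothing to see
  t_last_arrival <- pulse_center_time + depth_extent * 1e-6 / true_speed +
    3 * pulse_width
  t_window <- (n_frames - 1) * frame_interval
  if (pulse_center_time - 3 * pulse_width < 0 || t_last_arrival > t_window) {
    abort(sprintf(
      "pulse does not fit in the time window: arrivals span [%.3g, %.3g] s but the window is [0, %.3g] s.",
      pulse_center_time - 3 * pulse_width, t_last_arrival, t_window))
  }
  structure(
    list(true_speed = true_speed, depth_extent = depth_extent,
         n_depth = as.integer(n_depth), frame_interval = frame_interval,
         n_frames = as.integer(n_frames),
         pulse_center_time = pulse_center_time, pulse_width = pulse_width,
         displacement_amplitude = displacement_amplitude,
         refractive_index = refractive_index,
         center_wavelength = center_wavelength,
         phase_noise_std = phase_noise_std, seed = seed),
    class = "oce_sim_config"
  )
}

#' Simulate a phase-sensitive OCE depth-time map
#'
#' Forward model for the elastography chain: a Gaussian displacement pulse
#' propagating in depth at the configured speed, observed as wrapped optical
#' phase with additive Gaussian phase noise. The ground truth (speed,
#' noiseless displacement field parameters) is recorded in the map metadata,
#' so the inversion in [estimate_delays()] / [fit_wave_speed()] can be
#' scored by parameter recovery.
#'
#' @param config An [oce_sim_config()].
#' @param allow_wrapping If `FALSE` (default), refuse to generate a map
#'   whose noiseless phase magnitude exceeds `wrap_safety`: such a map
#'   would wrap and the simulation could not be inverted without phase
#'   unwrapping.
#' @param wrap_safety Wrap-safety bound in rad (default `pi`).
#' @return An [st_map()] with `kind = "phase"`.
#' @export
simulate_oce_map <- function(config, allow_wrapping = FALSE,
                             wrap_safety = pi) {
  stopifnot(inherits(config, "oce_sim_config"))
  pitch <- config$depth_extent / config$n_depth
  z_um <- (seq_len(config$n_depth) - 1) * pitch
  t_s <- (seq_len(config$n_frames) - 1) * config$frame_interval
  arrival <- config$pulse_center_time + z_um * 1e-6 / config$true_speed
  # displacement field u(z, t) in nm: Gaussian pulse per depth
  dt <- outer(arrival, t_s, function(a, t) t - a)
  u <- config$displacement_amplitude * exp(-dt^2 / (2 * config$pulse_width^2))
  phase <- 4 * pi * config$refractive_index * u / config$center_wavelength
  if (!allow_wrapping && max(abs(phase)) > wrap_safety) {
    abort(sprintf(
      "peak |phase| %.3g rad exceeds the wrap-safety bound %.3g; reduce `displacement_amplitude` or set `allow_wrapping = TRUE`.",
      max(abs(phase)), wrap_safety))
  }
  local_seed(config$seed)
  if (config$phase_noise_std > 0) {
    phase <- phase + rnorm(length(phase), sd = config$phase_noise_std)
  }
  st_map(
    wrap_phase(phase), kind = "phase", axial_pitch = pitch,
    frame_interval = config$frame_interval,
    center_wavelength = config$center_wavelength,
    refractive_index = config$refractive_index,
    metadata = list(true_speed = config$true_speed,
                    pulse_center_time = config$pulse_center_time,
                    pulse_width = config$pulse_width,
                    displacement_amplitude = config$displacement_amplitude,
                    phase_noise_std = config$phase_noise_std,
                    seed = config$seed)
  )
}
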