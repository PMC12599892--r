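#' Spatiotemporal depth-time map
#'
#' The input record of the elastography inversion: a depth-by-time array of
#' phase (rad) or axial displacement (nm), with the physical sampling
#' metadata needed to convert between the two and to fit a wave speed.
#'
#' @param values Numeric matrix, depth in rows, time in columns. At least
#'   8 x 8. Phase values must lie in (-pi, pi].
#' @param kind Either `"phase"` (rad) or `"displacement"` (nm).
#' @param axial_pitch Physical axial sampling pitch in um per depth sample
#'   (optical-path corrected, i.e. optical pitch divided by the refractive
#'   index).
#' @param frame_interval Time between frames in seconds.
#' @param center_wavelength Source center wavelength in nm (needed for
#'   phase-displacement conversion).
#' @param refractive_index Tissue refractive index (dimensionless).
#' @param metadata Free-form list; synthetic maps carry their ground truth
#'   here.
#'
#' @return An object of class `st_map`.
#' @seealso [simulate_oce_map()], [phase_to_displacement()],
#'   [estimate_delays()]
#' @export
st_map <- function(values, kind = c("phase", "displacement"),
                   axial_pitch, frame_interval,
                   center_wavelength = 1310, refractive_index = 1.38,
                   metadata = list()) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (depth x time).")
  }
  if (nrow(values) < 8L || ncol(values) < 8L) {
    abort("`values` needs at least 8 depth samples and 8 time samples.")
  }
  if (!all(is.finite(values))) abort("`values` must be finite.")
  if (axial_pitch <= 0) abort("`axial_pitch` must be positive.")
  if (frame_interval <= 0) abort("`frame_interval` must be positive.")
  if (kind == "phase" && (any(values > pi) || any(values <= -pi))) {
    abort("phase values must lie in (-pi, pi]; wrap before constructing.")
  }
  structure(
    list(values = values, kind = kind, axial_pitch = axial_pitch,
         frame_interval = frame_interval,
         center_wavelength = center_wavelength,
         refractive_index = refractive_index, metadata = metadata),
    class = "st_map"
  )
}

#' @export
print.st_map <- function(x, ...) {
  cat(sprintf(
    "<st_map> %d depths x %d frames (%s)\n  axial pitch %.3g um, frame interval %.3g us, depth extent %.3g um\n",
    nrow(x$values), ncol(x$values), x$kind, x$axial_pitch,
    x$frame_interval * 1e6, nrow(x$values) * x$axial_pitch))
  if (!is.null(x$metadata$true_speed)) {
    cat(sprintf("  synthetic ground truth: %.3g m/s\n", x$metadata$true_speed))
  }
  invisible(x)
}

#' Physical depth axis of a map (um)
#'
#' Depth of each row, `(i - 1) * axial_pitch`, in um.
#' @param map An [st_map()].
#' @return Numeric vector of depths in um.
#' @export
map_depths <- function(map) {
  (seq_len(nrow(map$values)) - 1) * map$axial_pitch
}

#' Time axis of a map (s)
#' @param map An [st_map()].
#' @return Numeric vector of frame times in seconds.
#' @export
map_times <- function(map) {
  (seq_len(ncol(map$values)) - 1) * map$frame_interval
}

#' @describeIn st_map Long-format tibble (`depth_um`, `time_s`, `value`,
#'   `kind`) for plotting and dplyr work.
#' @param x An `st_map`.
#' @param ... Unused.
#' @export
tidy.st_map <- function(x, ...) {
  tibble(
    depth_um = rep(map_depths(x), times = ncol(x$values)),
    time_s = rep(map_times(x), each = nrow(x$values)),
    value = as.vector(x$values),
    kind = x$kind
  )
}

#' Single-point Brillouin spectrum
#'
#' Intensity versus camera pixel from a two-stage VIPA spectrometer.
#' Each spectral order contains an anti-Stokes and a Stokes peak; their
#' intra-order pixel separation encodes the Brillouin shift.
#'
#' @param intensity Numeric vector of non-negative counts, length >= 64.
#' @param exposure Exposure time in seconds.
#' @param label Free-text label (e.g. material name).
#' @param metadata Free-form list; synthetic spectra carry ground truth here.
#' @return An object of class `brillouin_spectrum`.
#' @seealso [simulate_brillouin_spectrum()], [fit_spectral_peaks()]
#' @export
brillouin_spectrum <- function(intensity, exposure = 0.1, label = "",
                               metadata = list()) {
  if (!is.numeric(intensity) || length(intensity) < 64L) {
    abort("`intensity` must be a numeric vector of length >= 64.")
  }
  if (!all(is.finite(intensity)) || any(intensity < 0)) {
    abort("`intensity` must be finite and non-negative.")
  }
  structure(
    list(intensity = as.numeric(intensity),
         n_pixels = length(intensity),
         exposure = exposure, label = label, metadata = metadata),
    class = "brillouin_spectrum"
  )
}

#' @export
print.brillouin_spectrum <- function(x, ...) {
  cat(sprintf("<brillouin_spectrum> %d px%s, peak %.3g counts\n",
              x$n_pixels,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              max(x$intensity)))
  invisible(x)
}

#' @describeIn brillouin_spectrum Tibble with `pixel` and `intensity`
#'   columns.
#' @param x A `brillouin_spectrum`.
#' @param ... Unused.
#' @export
tidy.brillouin_spectrum <- function(x, ...) {
  tibble(pixel = seq_len(x$n_pixels), intensity = x$intensity)
}

#' Grayscale spheroid image
#'
#' A 2-D brightfield-style intensity image of one spheroid, used for size
#' monitoring alongside the mechanical measurements.
#'
#' @param pixels Numeric matrix of finite intensities.
#' @param pixel_size Physical pixel size in um/px.
#' @param acquisition_day Study day the image was taken (0, 4 or 7 in the
#'   default design).
#' @param sample_id Sample identifier.
#' @param metadata Free-form list (synthetic images carry ground truth).
#' @return An object of class `spheroid_image`.
#' @seealso [simulate_spheroid_image()], [segment_spheroid()]
#' @export
spheroid_image <- function(pixels, pixel_size = 1, acquisition_day = 0,
                           sample_id = "", metadata = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || !all(is.finite(pixels))) {
    abort("`pixels` must be a finite numeric matrix.")
  }
  if (pixel_size <= 0) abort("`pixel_size` must be positive.")
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         acquisition_day = acquisition_day, sample_id = sample_id,
         metadata = metadata),
    class = "spheroid_image"
  )
}

#' @export
print.spheroid_image <- function(x, ...) {
  cat(sprintf("<spheroid_image> %d x %d px at %.3g um/px (day %s, sample '%s')\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              format(x$acquisition_day), x$sample_id))
  invisible(x)
}
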