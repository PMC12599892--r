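#' Theoretical backscattering Brillouin shift
#'
#' In the backscattering geometry the Brillouin shift is
#' `Omega = 2 n v / lambda`: refractive index times acoustic velocity,
#' twice, over the optical wavelength. Used to derive the known shifts of
#' calibration liquids from tabulated material constants.
#'
#' @param refractive_index Refractive index (> 0), vectorized.
#' @param acoustic_velocity Acoustic (sound) velocity in m/s (>= 0).
#' @param wavelength Optical wavelength in nm (> 0).
#' @return Shift in GHz.
#' @examples
#' theoretical_shift(1.33, 1482, 660)  # water at 660 nm, ~5.97 GHz
#' @export
theoretical_shift <- function(refractive_index, acoustic_velocity,
                              wavelength) {
  if (any(refractive_index <= 0) || any(acoustic_velocity < 0) ||
      any(wavelength <= 0)) {
    abort("all arguments must be positive (acoustic_velocity may be 0).")
  }
  # with v in m/s and lambda in nm the 1e9 factors cancel, leaving GHz
  2 * refractive_index * acoustic_velocity / wavelength
}

#' Fit Lorentzian peaks to a spectrum
#'
#' Locates candidate peaks as local maxima after median-filter baseline
#' subtraction, then refines all of them jointly by Lorentzian least
#' squares (Levenberg-Marquardt) with a constant offset. Centers are
#' reported in pixels, sorted ascending, with standard errors from the fit
#' covariance.
#'
#' @param spectrum A [brillouin_spectrum()].
#' @param n_peaks Number of peaks expected (4 for a two-order VIPA
#'   spectrum, 2 for a single order).
#' @param baseline_halfwidth Half-width of the running-median baseline
#'   filter in pixels (default `n_pixels / 8`).
#' @param min_separation Minimum pixel separation between seeded peaks.
#' @param init_fwhm Initial FWHM guess in pixels for the optimizer.
#' @return A tibble with one row per peak: `center_px`, `center_se_px`,
#'   `fwhm_px`, `amplitude`; attribute `rmse` carries the fit RMSE in
#'   counts.
#' @export
fit_spectral_peaks <- function(spectrum, n_peaks = 4L,
                               baseline_halfwidth = NULL,
                               min_separation = 10, init_fwhm = 6) {
  stopifnot(inherits(spectrum, "brillouin_spectrum"))
  if (n_peaks < 1L) abort("`n_peaks` must be >= 1.")
  y <- spectrum$intensity
  n <- spectrum$n_pixels
  bw <- baseline_halfwidth %||% max(11, n %/% 8)
  k <- 2L * as.integer(bw) + 1L
  baseline <- runmed(y, min(k, if (n %% 2L) n else n - 1L))
  ys <- y - baseline
  seeds <- seed_peaks(ys, n_peaks, min_separation)
  if (length(seeds) < n_peaks) {
    abort(sprintf(
      "found only %d candidate peak(s)%s but `n_peaks` = %d%s.",
      length(seeds),
      if (length(seeds)) paste0(" (px ", paste(seeds, collapse = ", "), ")") else "",
      n_peaks,
      if (length(seeds) == 0L) "; no peaks found" else ""))
  }
  px <- seq_len(n)
  par0 <- c(stats::median(y),
            as.vector(rbind(ys[seeds], seeds, rep(init_fwhm, n_peaks))))
  model <- function(p) {
    out <- rep(p[1], n)
    for (j in seq_len(n_peaks)) {
      a <- p[3 * j - 1]; ctr <- p[3 * j]; w <- abs(p[3 * j + 1])
      out <- out + a * lorentzian(px, ctr, w)
    }
    out
  }
  fit <- minpack.lm::nls.lm(par0, fn = function(p) y - model(p),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$info %in% 1:4) {
    abort(sprintf("Lorentzian fit did not converge (info %d, residual RMSE %.3g counts).",
                  fit$info, sqrt(fit$deviance / n)))
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(par0)))
  p <- fit$par
  idx <- seq_len(n_peaks)
  out <- tibble(
    center_px = p[3 * idx],
    center_se_px = se[3 * idx],
    fwhm_px = abs(p[3 * idx + 1]),
    amplitude = p[3 * idx - 1]
  )
  out <- out[order(out$center_px), ]
  attr(out, "rmse") <- sqrt(fit$deviance / n)
  out
}

# Greedy local-maximum seeding: candidates must beat both neighbors, clear
# a noise-aware prominence floor, and respect a minimum mutual separation.
seed_peaks <- function(ys, n_peaks, min_separation) {
  n <- length(ys)
  sm <- runmed(ys, 3)
  is_max <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
                sm[2:(n - 1)] >= sm[3:n], FALSE)
  noise <- stats::mad(ys - sm)
  floor_h <- max(5 * noise, 0.05 * max(ys), .Machine$double.eps)
  cand <- which(is_max & sm > floor_h)
  cand <- cand[order(ys[cand], decreasing = TRUE)]
  picked <- integer(0)
  for (ci in cand) {
    if (length(picked) == n_peaks) break
    if (all(abs(ci - picked) >= min_separation)) picked <- c(picked, ci)
  }
  sort(picked)
}

#' Calibrate the spectral axis from reference liquids
#'
#' For a material of known shift `Omega`, the intra-order anti-Stokes /
#' Stokes peak pair is separated by `d = (FSR - 2 Omega) / dispersion`
#' pixels. Measuring `d` for two or more reference materials makes this a
#' linear system in `FSR / dispersion` (intercept) and `-2 / dispersion`
#' (slope), solved by least squares: closed-form, exactly determined at
#' two materials, overdetermined with residual diagnostics beyond that.
#'
#' @param calib_spectra List of [brillouin_spectrum()] objects, e.g. from
#'   [simulate_calibration_set()].
#' @param known_shifts Known shifts in GHz, one per spectrum; defaults to
#'   each spectrum's `metadata$known_shift`.
#' @param n_peaks Peaks fitted per spectrum (see [fit_spectral_peaks()]).
#' @param residual_tolerance RMS residual (GHz) above which a quality
#'   warning is recorded in the calibration object.
#' @param ... Passed to [fit_spectral_peaks()].
#' @return An object of class `spectral_calibration` with elements
#'   `dispersion` (GHz/px), `free_spectral_range` (GHz), `order_anchor`
#'   (px), `materials` (per-material tibble with separations and residuals),
#'   `rms_residual_ghz`, `quality_warning`.
#' @export
brillouin_calibrate <- function(calib_spectra, known_shifts = NULL,
                                n_peaks = 4L, residual_tolerance = 0.05,
                                ...) {
  if (!is.list(calib_spectra) || length(calib_spectra) < 2L) {
    abort("calibration needs at least 2 reference spectra.")
  }
  known_shifts <- known_shifts %||%
    purrr::map_dbl(calib_spectra, ~ .x$metadata$known_shift %||% NA_real_)
  if (anyNA(known_shifts)) {
    abort("`known_shifts` missing: supply them or tag spectra metadata with `known_shift`.")
  }
  if (length(unique(known_shifts)) < length(known_shifts)) {
    abort("duplicate known shifts: calibration system is degenerate.")
  }
  sep <- purrr::map(calib_spectra, function(sp) {
    pk <- fit_spectral_peaks(sp, n_peaks = n_peaks, ...)
    intra_order_separation(pk)
  })
  d_px <- purrr::map_dbl(sep, "separation_px")
  anchors <- purrr::map_dbl(sep, "anchor_px")
  fit <- lm(d_px ~ known_shifts)
  slope <- coef(fit)[["known_shifts"]]
  if (!is.finite(slope) || slope >= 0) {
    abort("calibration degenerate: separation must decrease with shift.")
  }
  dispersion <- -2 / slope
  fsr <- coef(fit)[[1]] * dispersion
  fitted_shift <- (fsr - dispersion * d_px) / 2
  resid_ghz <- known_shifts - fitted_shift
  rms <- sqrt(mean(resid_ghz^2))
  labels <- purrr::map_chr(calib_spectra, ~ .x$label %||% "")
  obj <- structure(
    list(dispersion = dispersion, free_spectral_range = fsr,
         order_anchor = mean(anchors),
         materials = tibble(material = labels, known_shift_ghz = known_shifts,
                            separation_px = d_px,
                            fitted_shift_ghz = fitted_shift,
                            residual_ghz = resid_ghz),
         rms_residual_ghz = rms,
         quality_warning = rms > residual_tolerance),
    class = "spectral_calibration"
  )
  if (obj$quality_warning) {
    warn(sprintf("calibration RMS residual %.3g GHz exceeds tolerance %.3g GHz.",
                 rms, residual_tolerance))
  }
  obj
}

# Intra-order separation from 4 sorted peak centers (two orders: pairs
# 1-2 and 3-4) or 2 centers (single order). The anchor is the midpoint of
# the first order's pair.
intra_order_separation <- function(peaks) {
  ctr <- peaks$center_px
  se <- peaks$center_se_px
  if (nrow(peaks) >= 4L) {
    seps <- c(ctr[2] - ctr[1], ctr[4] - ctr[3])
    sep_var <- sum(se[1:4]^2, na.rm = TRUE) / 4
    list(separation_px = mean(seps),
         separation_se_px = sqrt(sep_var),
         anchor_px = (ctr[1] + ctr[2]) / 2,
         fwhm_px = mean(peaks$fwhm_px))
  } else if (nrow(peaks) >= 2L) {
    list(separation_px = ctr[2] - ctr[1],
         separation_se_px = sqrt(sum(se[1:2]^2)),
         anchor_px = (ctr[1] + ctr[2]) / 2,
         fwhm_px = mean(peaks$fwhm_px))
  } else {
    abort("need at least 2 fitted peaks to measure a separation.")
  }
}

#' @export
print.spectral_calibration <- function(x, ...) {
  cat(sprintf(
    "<spectral_calibration> dispersion %.4g GHz/px, FSR %.4g GHz (%d materials, RMS residual %.3g GHz%s)\n",
    x$dispersion, x$free_spectral_range, nrow(x$materials),
    x$rms_residual_ghz, if (x$quality_warning) ", QUALITY WARNING" else ""))
  invisible(x)
}

#' @describeIn brillouin_calibrate Per-material separations, fitted shifts
#'   and residuals.
#' @param x A `spectral_calibration`.
#' @export
tidy.spectral_calibration <- function(x, ...) {
  x$materials
}

#' @describeIn brillouin_calibrate One-row summary of the calibration.
#' @export
glance.spectral_calibration <- function(x, ...) {
  tibble(dispersion_ghz_px = x$dispersion,
         free_spectral_range_ghz = x$free_spectral_range,
         order_anchor_px = x$order_anchor,
         n_materials = nrow(x$materials),
         rms_residual_ghz = x$rms_residual_ghz,
         quality_warning = x$quality_warning)
}

#' Extract the Brillouin shift from a spectrum
#'
#' Fits the anti-Stokes/Stokes peak pairs, measures their intra-order
#' pixel separation `d`, and inverts the calibration convention
#' `Omega = (FSR - dispersion * d) / 2`. The standard error propagates
#' from the fitted peak-center covariance; the linewidth is the mean
#' fitted Lorentzian FWHM converted to GHz.
#'
#' @param spectrum A [brillouin_spectrum()].
#' @param cal A `spectral_calibration` from [brillouin_calibrate()].
#' @param n_peaks Peaks to fit (default 4, i.e. both orders).
#' @param ... Passed to [fit_spectral_peaks()].
#' @return One-row tibble: `shift_ghz`, `shift_stderr_ghz`,
#'   `linewidth_ghz`, `fit_rmse`, `peaks_used`.
#' @export
brillouin_shift <- function(spectrum, cal, n_peaks = 4L, ...) {
  stopifnot(inherits(cal, "spectral_calibration"))
  pk <- fit_spectral_peaks(spectrum, n_peaks = n_peaks, ...)
  sep <- intra_order_separation(pk)
  shift <- (cal$free_spectral_range - cal$dispersion * sep$separation_px) / 2
  if (!is.finite(shift) || shift <= 0 || shift >= cal$free_spectral_range / 2) {
    abort(sprintf(
      "order ambiguity: decoded shift %.3g GHz is outside (0, FSR/2 = %.3g GHz).",
      shift, cal$free_spectral_range / 2))
  }
  tibble(
    shift_ghz = shift,
    shift_stderr_ghz = cal$dispersion * sep$separation_se_px / 2,
    linewidth_ghz = sep$fwhm_px * cal$dispersion,
    fit_rmse = attr(pk, "rmse"),
    peaks_used = nrow(pk)
  )
}

#' Map Brillouin shifts over a 2-D scan
#'
#' Applies [brillouin_shift()] at every grid point of a raster scan (e.g.
#' the central plane of a spheroid), flags points whose fit fails rather
#' than dropping them, and summarizes the shift over a region of interest.
#'
#' @param spectra_grid A matrix of [brillouin_spectrum()] objects built
#'   with `matrix(list(...), nrow, ncol)`, or any list with a `dim`
#'   attribute.
#' @param cal A `spectral_calibration`.
#' @param roi Optional logical matrix of the same dimensions selecting the
#'   region of interest; default: all points.
#' @param pixel_size Scan step in um.
#' @param ... Passed to [brillouin_shift()].
#' @return An object of class `brillouin_map` with matrices `shift`,
#'   `stderr`, `valid`, the ROI summary (`roi_mean_ghz`, `roi_sd_ghz`,
#'   `n_valid`, `invalid_fraction`) and `pixel_size`.
#' @export
map_shifts <- function(spectra_grid, cal, roi = NULL, pixel_size = 1, ...) {
  if (is.null(dim(spectra_grid))) {
    abort("`spectra_grid` must have a dim attribute (use matrix(list(...), nrow, ncol)).")
  }
  dims <- dim(spectra_grid)
  fits <- purrr::map(spectra_grid, function(sp) {
    tryCatch(brillouin_shift(sp, cal, ...),
             error = function(e) tibble(shift_ghz = NA_real_,
                                        shift_stderr_ghz = NA_real_,
                                        linewidth_ghz = NA_real_,
                                        fit_rmse = NA_real_,
                                        peaks_used = 0L))
  })
  shift <- matrix(purrr::map_dbl(fits, "shift_ghz"), dims[1], dims[2])
  stderr <- matrix(purrr::map_dbl(fits, "shift_stderr_ghz"), dims[1], dims[2])
  valid <- is.finite(shift)
  roi <- roi %||% matrix(TRUE, dims[1], dims[2])
  if (!identical(dim(roi), dims)) abort("`roi` dimensions must match the grid.")
  sel <- roi & valid
  if (!any(sel)) abort("no valid shift measurements inside the ROI.")
  vals <- shift[sel]
  structure(
    list(shift = shift, stderr = stderr, valid = valid, roi = roi,
         pixel_size = pixel_size,
         roi_mean_ghz = mean(vals),
         roi_sd_ghz = if (length(vals) > 1) sd(vals) else NA_real_,
         n_valid = sum(sel),
         invalid_fraction = 1 - sum(valid & roi) / sum(roi)),
    class = "brillouin_map"
  )
}

#' @export
print.brillouin_map <- function(x, ...) {
  cat(sprintf(
    "<brillouin_map> %d x %d points, ROI mean %.4g +/- %.2g GHz (n = %d, %.1f%% invalid)\n",
    nrow(x$shift), ncol(x$shift), x$roi_mean_ghz, x$roi_sd_ghz, x$n_valid,
    100 * x$invalid_fraction))
  invisible(x)
}

#' @describeIn map_shifts Long-format tibble of per-point shifts.
#' @param x A `brillouin_map`.
#' @export
tidy.brillouin_map <- function(x, ...) {
  dims <- dim(x$shift)
  tibble(
    row = rep(seq_len(dims[1]), times = dims[2]),
    col = rep(seq_len(dims[2]), each = dims[1]),
    x_um = (rep(seq_len(dims[2]), each = dims[1]) - 1) * x$pixel_size,
    y_um = (rep(seq_len(dims[1]), times = dims[2]) - 1) * x$pixel_size,
    shift_ghz = as.vector(x$shift),
    stderr_ghz = as.vector(x$stderr),
    valid = as.vector(x$valid),
    in_roi = as.vector(x$roi)
  )
}

#' @describeIn map_shifts One-row ROI summary.
#' @export
glance.brillouin_map <- function(x, ...) {
  tibble(roi_mean_ghz = x$roi_mean_ghz, roi_sd_ghz = x$roi_sd_ghz,
         n_valid = x$n_valid, invalid_fraction = x$invalid_fraction)
}
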