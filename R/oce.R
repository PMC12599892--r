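#' Convert a phase map to axial displacement
#'
#' Phase-sensitive OCT measures axial motion as an optical phase change;
#' the displacement in nm is `u = lambda0 * dphi / (4 pi n)` with source
#' wavelength `lambda0` and tissue refractive index `n`. An optional 1-D
#' temporal phase unwrap is applied per depth first, so displacements whose
#' phase excursion exceeds pi are still recovered; wrap corrections are
#' counted in the output metadata.
#'
#' @param map An [st_map()] with `kind = "phase"`.
#' @param unwrap Apply per-depth temporal phase unwrapping first (default
#'   `TRUE`).
#' @return An [st_map()] with `kind = "displacement"` (nm);
#'   `metadata$wrap_events` counts the unwrap corrections applied.
#' @examples
#' cfg <- oce_sim_config(phase_noise_std = 0)
#' u <- phase_to_displacement(simulate_oce_map(cfg))
#' @export
phase_to_displacement <- function(map, unwrap = TRUE) {
  stopifnot(inherits(map, "st_map"))
  if (map$kind != "phase") abort("`map` must have kind = \"phase\".")
  lam <- map$center_wavelength
  n <- map$refractive_index
  if (is.null(lam) || is.null(n) || !is.finite(lam) || !is.finite(n) ||
      lam <= 0 || n <= 0) {
    abort("`center_wavelength` and `refractive_index` must be set to convert phase to displacement.")
  }
  phase <- map$values
  wrap_events <- 0L
  if (unwrap) {
    for (i in seq_len(nrow(phase))) {
      uw <- unwrap_1d(phase[i, ])
      wrap_events <- wrap_events + uw$n_corrections
      phase[i, ] <- uw$x
    }
  }
  out <- map
  out$values <- lam * phase / (4 * pi * n)
  out$kind <- "displacement"
  out$metadata$wrap_events <- wrap_events
  out
}

# Classic 1-D phase unwrap: add multiples of 2*pi so successive differences
# stay within (-pi, pi].
unwrap_1d <- function(x) {
  d <- diff(x)
  jumps <- -round(d / (2 * pi))
  corr <- c(0, cumsum(jumps)) * 2 * pi
  list(x = x + corr, n_corrections = sum(jumps != 0))
}

#' Estimate per-depth shear-wave arrival delays
#'
#' The time-of-flight step of the elastography inversion. Each depth's
#' displacement waveform is compared against a reference depth's waveform
#' by normalized cross-correlation; the correlation peak lag, refined to
#' sub-frame precision by parabolic interpolation, is the propagation delay
#' of that depth relative to the reference. The peak correlation value is
#' kept as a per-depth quality score, which [fit_wave_speed()] uses to
#' drop unreliable depths.
#'
#' @param map An [st_map()] with `kind = "displacement"` (convert with
#'   [phase_to_displacement()] first).
#' @param reference_depth Reference depth in um; default: the shallowest
#'   retained depth.
#' @param window Optional time window `c(t_min, t_max)` in seconds to
#'   restrict the correlation to.
#' @param exclude_surface Fraction of the shallowest depths to drop
#'   (surface artifacts); default 0.1.
#' @return A tibble of class `delay_profile` with columns `depth_um`,
#'   `delay_s`, `quality`, and attributes `reference_depth_um` and
#'   `frame_interval`. Depths with flat (zero-variance) waveforms get
#'   `NA` delay and quality 0 rather than an error.
#' @export
estimate_delays <- function(map, reference_depth = NULL, window = NULL,
                            exclude_surface = 0.1) {
  stopifnot(inherits(map, "st_map"))
  if (map$kind != "displacement") {
    abort("`map` must have kind = \"displacement\"; run phase_to_displacement() first.")
  }
  depths <- map_depths(map)
  times <- map_times(map)
  vals <- map$values
  keep_depth <- depths >= stats::quantile(depths, exclude_surface)
  vals <- vals[keep_depth, , drop = FALSE]
  depths <- depths[keep_depth]
  if (!is.null(window)) {
    keep_t <- times >= window[1] & times <= window[2]
    if (sum(keep_t) < 8L) abort("`window` retains fewer than 8 frames.")
    vals <- vals[, keep_t, drop = FALSE]
  }
  reference_depth <- reference_depth %||% depths[1]
  iref <- which.min(abs(depths - reference_depth))
  ref <- vals[iref, ]
  if (sd(ref) == 0) {
    abort("reference depth has a flat waveform; choose another reference.")
  }
  res <- purrr::map(seq_len(nrow(vals)), function(i) {
    xcorr_delay(ref, vals[i, ], map$frame_interval)
  })
  out <- tibble(
    depth_um = depths,
    delay_s = purrr::map_dbl(res, "delay"),
    quality = purrr::map_dbl(res, "quality")
  )
  structure(out, class = c("delay_profile", class(out)),
            reference_depth_um = depths[iref],
            frame_interval = map$frame_interval)
}

# Normalized cross-correlation delay of y relative to x (positive: y lags
# x), with parabolic sub-sample refinement of the correlation peak.
xcorr_delay <- function(x, y, dt) {
  if (sd(y) == 0) return(list(delay = NA_real_, quality = 0))
  xc <- x - mean(x)
  yc <- y - mean(y)
  # cc[k] = sum_t xc(t) * yc(t + lag), lags -(n-1) .. (n-1)
  cc <- stats::convolve(yc, xc, conj = TRUE, type = "open")
  cc <- cc / sqrt(sum(xc^2) * sum(yc^2))
  n <- length(x)
  lags <- seq.int(-(n - 1L), n - 1L)
  k <- which.max(cc)
  peak <- cc[k]
  offset <- 0
  if (k > 1L && k < length(cc)) {
    denom <- cc[k - 1L] - 2 * cc[k] + cc[k + 1L]
    if (denom < 0) offset <- 0.5 * (cc[k - 1L] - cc[k + 1L]) / denom
    offset <- max(min(offset, 0.5), -0.5)
  }
  list(delay = (lags[k] + offset) * dt, quality = peak)
}

#' Fit wave speed from a delay-versus-depth profile
#'
#' Fits `delay = a + b * depth` over the depths whose correlation quality
#' clears `min_quality`; the wave speed is the inverse slope `1 / b`. The
#' slope must be positive -- the wave travels toward increasing delay with
#' depth -- otherwise no propagating wave was detected. The speed standard
#' error is propagated from the slope standard error by the delta method,
#' `se(c) = se(b) / b^2`.
#'
#' @param profile A `delay_profile` from [estimate_delays()].
#' @param min_quality Minimum correlation quality to retain a depth
#'   (default 0.5).
#' @param method `"ols"` (default) or `"theil_sen"` (median of pairwise
#'   slopes; robust to outlier depths, no closed-form standard error).
#' @return One-row tibble: `wave_speed_mps`, `speed_stderr_mps`,
#'   `r_squared`, `n_depths_used`, `method`.
#' @export
fit_wave_speed <- function(profile, min_quality = 0.5,
                           method = c("ols", "theil_sen")) {
  method <- match.arg(method)
  keep <- is.finite(profile$delay_s) & profile$quality >= min_quality
  d <- profile[keep, ]
  if (nrow(d) < 3L) {
    abort(sprintf("insufficient data: only %d usable depths (need >= 3).",
                  nrow(d)))
  }
  z_m <- d$depth_um * 1e-6
  if (sd(d$delay_s) == 0) {
    abort("no propagating wave detected: delays are constant across depth.")
  }
  if (method == "ols") {
    fit <- lm(delay_s ~ z_m, data = tibble(delay_s = d$delay_s, z_m = z_m))
    b <- coef(fit)[["z_m"]]
    rss <- sum(stats::residuals(fit)^2)
    se_b <- sqrt(rss / (nrow(d) - 2) / sum((z_m - mean(z_m))^2))
    r2 <- 1 - rss / sum((d$delay_s - mean(d$delay_s))^2)
  } else {
    pairs <- combn(nrow(d), 2)
    slopes <- (d$delay_s[pairs[2, ]] - d$delay_s[pairs[1, ]]) /
      (z_m[pairs[2, ]] - z_m[pairs[1, ]])
    b <- median(slopes)
    a <- median(d$delay_s - b * z_m)
    res <- d$delay_s - (a + b * z_m)
    r2 <- max(0, min(1, 1 - sum(res^2) / sum((d$delay_s - mean(d$delay_s))^2)))
    se_b <- NA_real_
  }
  if (!is.finite(b) || b <= 0) {
    abort("no propagating wave detected: delay-depth slope is not positive.")
  }
  tibble(
    wave_speed_mps = 1 / b,
    speed_stderr_mps = if (is.finite(se_b)) se_b / b^2 else NA_real_,
    r_squared = r2,
    n_depths_used = nrow(d),
    method = method
  )
}

#' Young's modulus from shear-wave speed
#'
#' The bulk shear-wave relation `c = sqrt(G / rho)` with
#' `G = E / (2 (1 + nu))` gives `E = 2 rho (1 + nu) c^2`. With the default
#' soft-tissue parameters (density 1000 kg/m^3, Poisson's ratio 0.49) this
#' is `E = 2980 c^2` Pa for `c` in m/s.
#'
#' @param speed Wave speed(s) in m/s, non-negative.
#' @param density Mass density in kg/m^3 (> 0).
#' @param poisson_ratio Poisson's ratio, in `[0, 0.5)`.
#' @return Young's modulus in Pa (vectorized over `speed`).
#' @examples
#' young_modulus(1)    # 2980 Pa
#' young_modulus(2.5)  # 18625 Pa
#' @export
young_modulus <- function(speed, density = 1000, poisson_ratio = 0.49) {
  check_scalar(density, "density", lower = 0, strict_lower = TRUE)
  check_scalar(poisson_ratio, "poisson_ratio", lower = 0)
  if (poisson_ratio >= 0.5) {
    abort("`poisson_ratio` must be below 0.5 (incompressible limit).")
  }
  if (any(!is.finite(speed)) || any(speed < 0)) {
    abort("`speed` must be finite and non-negative.")
  }
  2 * density * (1 + poisson_ratio) * speed^2
}

#' Full elastography analysis of one (triplicate) measurement
#'
#' Runs the whole chain -- phase-to-displacement conversion, delay
#' estimation, speed fit -- on each replicate map, aggregates replicate
#' speeds as mean and SD, and converts the mean speed to Young's modulus.
#' Replicates that fail (e.g. no detectable wave) are dropped with a
#' warning and their failure reasons retained; the measurement fails only
#' if every replicate does.
#'
#' @param maps A single [st_map()] or a list of replicate maps (phase or
#'   displacement kind).
#' @param density,poisson_ratio Passed to [young_modulus()].
#' @param min_quality,method Passed to [fit_wave_speed()].
#' @param ... Passed to [estimate_delays()].
#' @return An object of class `elasticity_result`; see [tidy()] for
#'   per-replicate rows and [glance()] for the one-row summary.
#' @export
analyze_oce_measurement <- function(maps, density = 1000,
                                    poisson_ratio = 0.49,
                                    min_quality = 0.5, method = "ols", ...) {
  if (inherits(maps, "st_map")) maps <- list(maps)
  if (length(maps) < 1L) abort("need at least one map.")
  reps <- purrr::imap(maps, function(map, i) {
    res <- tryCatch({
      if (map$kind == "phase") map <- phase_to_displacement(map)
      fit <- fit_wave_speed(estimate_delays(map, ...),
                            min_quality = min_quality, method = method)
      dplyr::mutate(fit, replicate = i, status = "ok", reason = NA_character_,
                    .before = 1)
    }, error = function(e) {
      tibble(replicate = i, status = "failed", reason = conditionMessage(e),
             wave_speed_mps = NA_real_, speed_stderr_mps = NA_real_,
             r_squared = NA_real_, n_depths_used = NA_integer_,
             method = method)
    })
    res
  })
  reps <- dplyr::bind_rows(reps)
  ok <- reps$status == "ok"
  if (!any(ok)) {
    abort(paste0("all replicates failed:\n",
                 paste0("  replicate ", reps$replicate, ": ", reps$reason,
                        collapse = "\n")))
  }
  if (any(!ok)) {
    warn(sprintf("%d of %d replicates failed and were dropped.",
                 sum(!ok), nrow(reps)))
  }
  speeds <- reps$wave_speed_mps[ok]
  mean_speed <- mean(speeds)
  structure(
    list(replicates = reps,
         wave_speed_mps = mean_speed,
         speed_sd_mps = if (length(speeds) > 1) sd(speeds) else NA_real_,
         young_modulus_pa = young_modulus(mean_speed, density, poisson_ratio),
         density = density, poisson_ratio = poisson_ratio,
         n_replicates_used = sum(ok)),
    class = "elasticity_result"
  )
}

#' @export
print.elasticity_result <- function(x, ...) {
  cat(sprintf(
    "<elasticity_result> c = %.3g %s m/s (n = %d), E = %.3g Pa (rho = %g, nu = %g)\n",
    x$wave_speed_mps,
    if (is.finite(x$speed_sd_mps)) sprintf("+/- %.2g", x$speed_sd_mps) else "",
    x$n_replicates_used, x$young_modulus_pa, x$density, x$poisson_ratio))
  invisible(x)
}

#' @describeIn analyze_oce_measurement Per-replicate speeds and fit
#'   diagnostics as a tibble.
#' @param x An `elasticity_result`.
#' @export
tidy.elasticity_result <- function(x, ...) {
  x$replicates
}

#' @describeIn analyze_oce_measurement One-row summary (mean speed, SD,
#'   Young's modulus, parameters used).
#' @export
glance.elasticity_result <- function(x, ...) {
  tibble(
    wave_speed_mps = x$wave_speed_mps, speed_sd_mps = x$speed_sd_mps,
    young_modulus_pa = x$young_modulus_pa,
    n_replicates_used = x$n_replicates_used,
    density = x$density, poisson_ratio = x$poisson_ratio
  )
}
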