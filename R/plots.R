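#' @importFrom ggplot2 ggplot aes geom_raster geom_line geom_point
#'   geom_errorbar geom_hline labs scale_fill_viridis_c facet_wrap
#'   theme_minimal position_dodge
NULL

#' Plot a depth-time map
#'
#' Raster of the phase or displacement field, time on the x axis and depth
#' increasing downward -- the standard orientation for wavefront plots,
#' where a propagating wave appears as a slanted band whose slope is the
#' inverse speed.
#'
#' @param object An [st_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.st_map <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$time_s * 1e6, y = .data$depth_um,
                 fill = .data$value)) +
    geom_raster() +
    ggplot2::scale_y_reverse() +
    scale_fill_viridis_c(name = if (object$kind == "phase") "phase (rad)"
                         else "u (nm)") +
    labs(x = "time (µs)", y = "depth (µm)") +
    theme_minimal()
}

#' Plot a delay profile
#'
#' Arrival delay versus depth with the per-depth correlation quality; the
#' slope of this line is the inverse wave speed.
#'
#' @param object A `delay_profile` from [estimate_delays()].
#' @param min_quality Depths below this quality are shown hollow.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.delay_profile <- function(object, min_quality = 0.5, ...) {
  df <- tibble(depth_um = object$depth_um, delay_us = object$delay_s * 1e6,
               quality = object$quality,
               used = is.finite(object$delay_s) &
                 object$quality >= min_quality)
  ggplot(df, aes(x = .data$depth_um, y = .data$delay_us,
                 colour = .data$quality, shape = .data$used)) +
    geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "used in fit") +
    ggplot2::scale_colour_viridis_c(name = "NCC peak") +
    labs(x = "depth (µm)", y = "delay (µs)") +
    theme_minimal()
}

#' Plot a Brillouin spectrum
#'
#' Intensity versus camera pixel; with `peaks` supplied (from
#' [fit_spectral_peaks()]) the fitted centers are marked.
#'
#' @param object A [brillouin_spectrum()].
#' @param peaks Optional peak tibble from [fit_spectral_peaks()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.brillouin_spectrum <- function(object, peaks = NULL, ...) {
  p <- ggplot(tidy(object), aes(x = .data$pixel, y = .data$intensity)) +
    geom_line() +
    labs(x = "pixel", y = "counts", title = object$label) +
    theme_minimal()
  if (!is.null(peaks)) {
    p <- p + ggplot2::geom_vline(xintercept = peaks$center_px,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot a Brillouin shift map
#'
#' @param object A `brillouin_map` from [map_shifts()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.brillouin_map <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$x_um, y = .data$y_um, fill = .data$shift_ghz)) +
    geom_raster() +
    scale_fill_viridis_c(name = "shift (GHz)", na.value = "grey80") +
    labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::coord_equal() +
    theme_minimal()
}

#' Plot a study report
#'
#' The normalized treated/control ratio per group over the study days,
#' with propagated-SD error bars and the no-effect line at 1.
#'
#' @param object A `study_report` from [summarize_study()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.study_report <- function(object, ...) {
  df <- object$normalized
  ggplot(df, aes(x = .data$day, y = .data$ratio, colour = .data$group)) +
    geom_hline(yintercept = 1, linetype = "dotted") +
    geom_line(position = position_dodge(width = 0.3)) +
    geom_point(position = position_dodge(width = 0.3)) +
    geom_errorbar(aes(ymin = .data$ratio - .data$ratio_sd,
                      ymax = .data$ratio + .data$ratio_sd),
                  width = 0.4, position = position_dodge(width = 0.3)) +
    labs(x = "day", y = "treated / control ratio",
         title = sprintf("Normalized treatment effect (%s)", object$metric)) +
    theme_minimal()
}
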