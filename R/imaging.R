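#' Average repeated B-scans
#'
#' Pixelwise mean of repeated acquisitions of the same frame, the standard
#' post-processing step to enhance SNR (three repeats in the emulated
#' protocol). Single-frame noise is estimated from the residuals around
#' the mean; for independent noise the averaged frame's noise is that
#' estimate over `sqrt(N)`, an SNR gain of `sqrt(N)`.
#'
#' @param frames List of >= 2 numeric matrices of identical dimensions.
#' @return A list of class `bscan_average`: `average` (matrix),
#'   `n_frames`, `noise_sd_frame` (estimated single-frame noise SD),
#'   `noise_sd_average` (predicted noise SD of the average), `snr_gain`
#'   (`sqrt(N)`, or `NA` with a warning when the frames are identical and
#'   the noise estimate degenerates).
#' @examples
#' fr <- replicate(3, matrix(rnorm(64, 10), 8, 8), simplify = FALSE)
#' avg <- average_repeats(fr)
#' @export
average_repeats <- function(frames) {
  if (!is.list(frames) || length(frames) < 2L) {
    abort("`frames` must be a list of at least 2 arrays.")
  }
  dims <- dim(frames[[1]])
  ok <- purrr::map_lgl(frames, ~ is.numeric(.x) && identical(dim(.x), dims))
  if (!all(ok)) abort("all frames must be numeric arrays of identical shape.")
  n <- length(frames)
  avg <- Reduce(`+`, frames) / n
  # residual variance around the mean underestimates the single-frame
  # noise variance by (n-1)/n; correct for it
  resid_var <- mean(purrr::map_dbl(frames, ~ mean((.x - avg)^2)))
  sigma2 <- resid_var * n / (n - 1)
  if (sigma2 <= 0) {
    warn("frames are identical: SNR gain is undefined.")
    gain <- NA_real_
    sd_avg <- 0
  } else {
    gain <- sqrt(n)
    sd_avg <- sqrt(sigma2 / n)
  }
  structure(
    list(average = avg, n_frames = n, noise_sd_frame = sqrt(max(sigma2, 0)),
         noise_sd_average = sd_avg, snr_gain = gain),
    class = "bscan_average"
  )
}

#' @export
print.bscan_average <- function(x, ...) {
  cat(sprintf(
    "<bscan_average> %d frames, frame noise SD %.3g -> %.3g (SNR gain %s)\n",
    x$n_frames, x$noise_sd_frame, x$noise_sd_average,
    if (is.finite(x$snr_gain)) sprintf("%.2f", x$snr_gain) else "undefined"))
  invisible(x)
}

#' Segment a spheroid and measure its morphology
#'
#' Global thresholding by maximizing between-class variance (Otsu), then
#' the largest 8-connected foreground component with holes filled. The
#' foreground class is taken as the minority class (`"auto"`), or forced
#' bright/dark. Metrics come out in physical units via the image's
#' `pixel_size`: area, equivalent diameter `2 sqrt(area / pi)`, centroid,
#' and circularity `4 pi area / perimeter^2` (clamped to 1; rasterized
#' perimeters carry a few percent discretization error).
#'
#' @param image A [spheroid_image()].
#' @param foreground `"auto"` (minority class), `"bright"` or `"dark"`.
#' @return An object of class `spheroid_morphology` with fields
#'   `area_um2`, `equivalent_diameter_um`, `centroid_px` (row, col),
#'   `circularity`, `mask` (logical matrix), plus the image's identifiers.
#'   Fails with "segmentation failed" if the image has no contrast or the
#'   two intensity classes are not separable above the noise.
#' @export
segment_spheroid <- function(image, foreground = c("auto", "bright", "dark")) {
  stopifnot(inherits(image, "spheroid_image"))
  foreground <- match.arg(foreground)
  px <- image$pixels
  rng <- range(px)
  if (diff(rng) <= 0) {
    abort("segmentation failed: image has no intensity range.")
  }
  norm <- (px - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  hi <- norm > thr
  # separability check: class means must differ by more than the
  # within-class spread, otherwise the split is just noise
  mu_hi <- mean(norm[hi]); mu_lo <- mean(norm[!hi])
  sd_w <- max(sd(norm[hi]), sd(norm[!hi]), 0)
  if (!is.finite(mu_hi) || !is.finite(mu_lo) ||
      (mu_hi - mu_lo) <= 3 * sd_w) {
    abort("segmentation failed: foreground and background are not separable.")
  }
  fg <- switch(foreground,
               bright = hi,
               dark = !hi,
               auto = if (sum(hi) <= sum(!hi)) hi else !hi)
  if (!any(fg)) abort("segmentation failed: no foreground after threshold.")
  lab <- label_components8(fg)
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0
  mask <- matrix(as.logical(mask), nrow(px), ncol(px))
  area_px <- sum(mask)
  shp <- EBImage::computeFeatures.shape(EBImage::Image(mask * 1))
  perimeter_px <- shp[1, "s.perimeter"]
  circ <- min(1, 4 * pi * area_px / perimeter_px^2)
  idx <- which(mask, arr.ind = TRUE)
  ps <- image$pixel_size
  structure(
    list(area_um2 = area_px * ps^2,
         equivalent_diameter_um = 2 * sqrt(area_px * ps^2 / pi),
         centroid_px = c(row = mean(idx[, 1]), col = mean(idx[, 2])),
         circularity = circ,
         mask = mask,
         pixel_size = ps,
         acquisition_day = image$acquisition_day,
         sample_id = image$sample_id),
    class = "spheroid_morphology"
  )
}

# 8-connected labeling: EBImage's fast 4-connected pass, then union-find
# merging of labels that touch diagonally.
label_components8 <- function(fg) {
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- matrix(as.integer(lab), nrow(fg), ncol(fg))
  nmax <- max(lab)
  if (nmax <= 1L) return(lab)
  parent <- seq_len(nmax)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (dc in c(-1L, 1L)) {
    a <- lab[-nr, (1:nc)[(1:nc) + dc >= 1 & (1:nc) + dc <= nc]]
    b <- lab[-1, (1:nc)[(1:nc) + dc >= 1 & (1:nc) + dc <= nc] + dc]
    touch <- a > 0 & b > 0 & a != b
    for (k in which(touch)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nmax), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- relab[lab[lab > 0]]
  lab
}

#' @export
print.spheroid_morphology <- function(x, ...) {
  cat(sprintf(
    "<spheroid_morphology> area %.4g um^2, eq. diameter %.4g um, circularity %.3f\n",
    x$area_um2, x$equivalent_diameter_um, x$circularity))
  invisible(x)
}

#' @describeIn segment_spheroid One-row tibble of the morphology metrics.
#' @param x A `spheroid_morphology`.
#' @param ... Unused.
#' @export
tidy.spheroid_morphology <- function(x, ...) {
  tibble(
    sample_id = x$sample_id, day = x$acquisition_day,
    area_um2 = x$area_um2, eq_diameter_um = x$equivalent_diameter_um,
    circularity = x$circularity,
    centroid_row = x$centroid_px[["row"]],
    centroid_col = x$centroid_px[["col"]]
  )
}

#' Track spheroid size across study days
#'
#' Builds per-sample size trajectories and the relative size versus day 0,
#' `diameter(day) / diameter(0)` -- the growth/shrinkage readout that
#' accompanies the mechanical measurements.
#'
#' @param morphologies Either a list of `spheroid_morphology` objects or a
#'   tibble with columns `sample_id`, `day`, `eq_diameter_um` (as produced
#'   by [tidy()] on segmentations).
#' @return A tibble `sample_id`, `day`, `eq_diameter_um`,
#'   `relative_size`; errors if any sample lacks a day-0 entry.
#' @export
track_size <- function(morphologies) {
  tbl <- if (is.data.frame(morphologies)) {
    as_tibble(morphologies)
  } else {
    dplyr::bind_rows(purrr::map(morphologies, tidy))
  }
  need <- c("sample_id", "day", "eq_diameter_um")
  if (!all(need %in% names(tbl))) {
    abort("need columns sample_id, day, eq_diameter_um.")
  }
  no_d0 <- tbl |>
    dplyr::summarise(has0 = any(.data$day == 0), .by = "sample_id") |>
    dplyr::filter(!.data$has0)
  if (nrow(no_d0) > 0) {
    abort(sprintf("missing day-0 entry for sample(s): %s.",
                  paste(no_d0$sample_id, collapse = ", ")))
  }
  tbl |>
    dplyr::mutate(
      relative_size = .data$eq_diameter_um /
        .data$eq_diameter_um[.data$day == 0][1],
      .by = "sample_id"
    ) |>
    dplyr::arrange(.data$sample_id, .data$day) |>
    dplyr::select(dplyr::all_of(c(need, "relative_size")))
}
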