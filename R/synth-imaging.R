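#' Simulate a brightfield-style spheroid image
#'
#' A centered disk of known diameter on a uniform background with additive
#' Gaussian noise -- the fixture against which the segmentation chain is
#' scored. The exact rasterized disk area (pixel count) is stored in the
#' metadata as the segmentation oracle.
#'
#' @param diameter_px Disk diameter in pixels (must be smaller than
#'   `image_size`).
#' @param image_size Side length of the square image in pixels.
#' @param foreground,background Intensity levels of disk and background.
#' @param noise_std Additive Gaussian noise sigma.
#' @param pixel_size Physical pixel size in um/px.
#' @param acquisition_day,sample_id Passed through to the image record.
#' @param seed RNG seed or NULL.
#' @return A [spheroid_image()]; metadata holds `true_diameter_px`,
#'   `true_area_px` (rasterized pixel count) and the intensity levels.
#' @examples
#' img <- simulate_spheroid_image(100, image_size = 192, seed = 1)
#' @export
simulate_spheroid_image <- function(diameter_px, image_size = 256L,
                                    foreground = 0.8, background = 0.2,
                                    noise_std = 0.02, pixel_size = 2,
                                    acquisition_day = 0, sample_id = "",
                                    seed = NULL) {
  check_scalar(diameter_px, "diameter_px", lower = 0, strict_lower = TRUE)
  check_scalar(image_size, "image_size", lower = 16)
  if (diameter_px >= image_size) {
    abort("`diameter_px` must be smaller than `image_size`.")
  }
  n <- as.integer(image_size)
  ctr <- (n + 1) / 2
  r <- diameter_px / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  disk <- d2 <= r^2
  img <- matrix(background, n, n)
  img[disk] <- foreground
  local_seed(seed)
  if (noise_std > 0) img <- img + rnorm(length(img), sd = noise_std)
  spheroid_image(
    img, pixel_size = pixel_size, acquisition_day = acquisition_day,
    sample_id = sample_id,
    metadata = list(true_diameter_px = diameter_px,
                    true_area_px = sum(disk),
                    foreground = foreground, background = background,
                    noise_std = noise_std, seed = seed)
  )
}
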