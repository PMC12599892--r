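#' Read and write study tables as CSV
#'
#' Long-format CSV with header
#' `group,condition,day,replicate,metric,value`.
#'
#' @param table A study tibble (see [simulate_study_table()]).
#' @param path File path.
#' @return `read_study_table()` returns the validated tibble;
#'   `write_study_table()` returns `table` invisibly.
#' @export
write_study_table <- function(table, path) {
  table <- validate_study_table(table)
  readr::write_csv(table[, c("group", "condition", "day", "replicate",
                             "metric", "value")], path)
  invisible(table)
}

#' @rdname write_study_table
#' @export
read_study_table <- function(path) {
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      group = readr::col_character(), condition = readr::col_character(),
      day = readr::col_double(), replicate = readr::col_character(),
      metric = readr::col_character(), value = readr::col_double()
    )
  )
  validate_study_table(tbl)
}

#' Read and write spectra as CSV
#'
#' Two-column CSV (`pixel`, `intensity`); metadata beyond the label is not
#' persisted.
#'
#' @param spectrum A [brillouin_spectrum()].
#' @param path File path.
#' @param label,exposure Metadata attached on read.
#' @return The spectrum (invisibly for write).
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "brillouin_spectrum"))
  readr::write_csv(tidy(spectrum), path)
  invisible(spectrum)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path, label = "", exposure = 0.1) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    pixel = readr::col_double(), intensity = readr::col_double()))
  brillouin_spectrum(tbl$intensity[order(tbl$pixel)], exposure = exposure,
                     label = label)
}

#' Read and write depth-time maps as TIFF with a sidecar
#'
#' The array goes to a 32-bit float TIFF; the sampling metadata (kind,
#' axial pitch, frame interval, wavelength, refractive index) goes to a
#' `key = value` text sidecar at `paste0(path, ".meta")`.
#'
#' @param map An [st_map()].
#' @param path TIFF file path.
#' @return The map (invisibly for write).
#' @export
write_st_map <- function(map, path) {
  stopifnot(inherits(map, "st_map"))
  # TIFF samples are stored as unsigned integers in [0, 1]; rescale and
  # keep the range in the sidecar (32-bit depth keeps ~1e-9 resolution)
  vmin <- min(map$values)
  vmax <- max(map$values)
  scaled <- if (vmax > vmin) (map$values - vmin) / (vmax - vmin)
            else map$values * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- c(kind = map$kind, axial_pitch = map$axial_pitch,
            frame_interval = map$frame_interval,
            center_wavelength = map$center_wavelength,
            refractive_index = map$refractive_index,
            value_min = vmin, value_max = vmax)
  writeLines(paste(names(meta), unname(meta), sep = " = "),
             paste0(path, ".meta"))
  invisible(map)
}

#' @rdname write_st_map
#' @export
read_st_map <- function(path) {
  vals <- tiff::readTIFF(path)
  meta <- read_keyvalue(paste0(path, ".meta"))
  vmin <- as.numeric(meta$value_min)
  vmax <- as.numeric(meta$value_max)
  vals <- if (vmax > vmin) vals * (vmax - vmin) + vmin else vals + vmin
  # quantization can push phase a hair past the wrap boundary
  if (identical(meta$kind, "phase")) vals <- wrap_phase(vals)
  st_map(vals, kind = meta$kind,
         axial_pitch = as.numeric(meta$axial_pitch),
         frame_interval = as.numeric(meta$frame_interval),
         center_wavelength = as.numeric(meta$center_wavelength),
         refractive_index = as.numeric(meta$refractive_index))
}

#' Read and write spectrometer calibrations as key-value text
#'
#' @param cal A `spectral_calibration` from [brillouin_calibrate()].
#' @param path File path.
#' @return The calibration (invisibly for write).
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "spectral_calibration"))
  lines <- c(
    paste("dispersion =", format(cal$dispersion, digits = 15)),
    paste("free_spectral_range =", format(cal$free_spectral_range, digits = 15)),
    paste("order_anchor =", format(cal$order_anchor, digits = 15)),
    paste("rms_residual_ghz =", format(cal$rms_residual_ghz, digits = 15)),
    paste("quality_warning =", cal$quality_warning),
    paste("materials =", paste(cal$materials$material, collapse = ",")),
    paste("known_shifts_ghz =",
          paste(format(cal$materials$known_shift_ghz, digits = 15),
                collapse = ",")),
    paste("separations_px =",
          paste(format(cal$materials$separation_px, digits = 15),
                collapse = ","))
  )
  writeLines(lines, path)
  invisible(cal)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  kv <- read_keyvalue(path)
  sep_px <- as.numeric(strsplit(kv$separations_px, ",")[[1]])
  known <- as.numeric(strsplit(kv$known_shifts_ghz, ",")[[1]])
  disp <- as.numeric(kv$dispersion)
  fsr <- as.numeric(kv$free_spectral_range)
  fitted <- (fsr - disp * sep_px) / 2
  structure(
    list(dispersion = disp, free_spectral_range = fsr,
         order_anchor = as.numeric(kv$order_anchor),
         materials = tibble(material = strsplit(kv$materials, ",")[[1]],
                            known_shift_ghz = known,
                            separation_px = sep_px,
                            fitted_shift_ghz = fitted,
                            residual_ghz = known - fitted),
         rms_residual_ghz = as.numeric(kv$rms_residual_ghz),
         quality_warning = as.logical(kv$quality_warning)),
    class = "spectral_calibration"
  )
}

read_keyvalue <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\\s*=\\s*")
  setNames(lapply(parts, function(p) paste(p[-1], collapse = " ")),
           vapply(parts, `[[`, "", 1))
}

#' Read a spheroid image from TIFF or PNG
#'
#' Grayscale images are read as-is; RGB(A) images are averaged over
#' channels.
#'
#' @param path File path ending in `.tif(f)` or `.png`.
#' @param pixel_size,acquisition_day,sample_id Image metadata (see
#'   [spheroid_image()]).
#' @return A [spheroid_image()].
#' @export
read_spheroid_image <- function(path, pixel_size = 1, acquisition_day = 0,
                                sample_id = "") {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               tif = , tiff = tiff::readTIFF(path),
               png = png::readPNG(path),
               abort(sprintf("unsupported image extension '%s'.", ext)))
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)
  spheroid_image(px, pixel_size = pixel_size,
                 acquisition_day = acquisition_day, sample_id = sample_id)
}

#' Write a segmentation mask as PNG
#'
#' @param morphology A `spheroid_morphology` from [segment_spheroid()].
#' @param path PNG file path.
#' @return The morphology, invisibly.
#' @export
write_mask_png <- function(morphology, path) {
  stopifnot(inherits(morphology, "spheroid_morphology"))
  png::writePNG(morphology$mask * 1, path)
  invisible(morphology)
}
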