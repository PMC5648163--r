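#' Grey-to-density calibration lines
#'
#' Synchrotron scans with a monochromatic beam admit a linear map from pixel
#' grey value to hydroxyapatite density, `rho = slope * grey + intercept`
#' (g/cm^3). The two scan batches have their own lines: batch 1 uses
#' `rho = 6.9e-5 * Px + 1.54`, batch 2 `rho = 2.8e-4 * Px + 1.49`.
#'
#' @param batch Scan batch, 1 or 2.
#' @param slope,intercept Optional overrides of the batch defaults.
#' @return An object of class `calibration_params` with fields `slope`,
#'   `intercept`, `batch_id`.
#' @export
calibration_params <- function(batch = 1, slope = NULL, intercept = NULL) {
  stopifnot(batch %in% c(1, 2))
  defaults <- list(`1` = c(6.9e-5, 1.54), `2` = c(2.8e-4, 1.49))
  d <- defaults[[as.character(batch)]]
  slope <- slope %||% d[1]
  intercept <- intercept %||% d[2]
  stopifnot(slope > 0)
  structure(list(slope = slope, intercept = intercept, batch_id = batch),
            class = "calibration_params")
}

#' Calibration line used for rendering synthetic sections
#'
#' The empirical batch lines have intercepts near 1.5 g/cm^3 and cannot
#' represent freshly secreted enamel (~0.65 g/cm^3) without clipping; the
#' synthetic line spans \[0, 2.62\] g/cm^3 across the 16-bit grey range
#' (with headroom for measurement noise) so noise-free renders round-trip
#' exactly.
#'
#' @param batch Batch id to stamp on rendered sections.
#' @param max_density Density mapped to grey 50000, g/cm^3.
#' @return A `calibration_params` object.
#' @export
synthetic_calibration <- function(batch = 1, max_density = 2.62) {
  structure(list(slope = max_density / 50000, intercept = 0,
                 batch_id = batch),
            class = "calibration_params")
}

#' Convert pixel grey values to hydroxyapatite density
#'
#' @param px Grey values (>= 0).
#' @param calib A [calibration_params()] object.
#' @return Densities in g/cm^3, `slope * px + intercept`.
#' @export
grey_to_density <- function(px, calib) {
  stopifnot(inherits(calib, "calibration_params"))
  if (any(px < 0, na.rm = TRUE)) {
    stop("grey values must be non-negative", call. = FALSE)
  }
  calib$slope * px + calib$intercept
}

#' Calibrate a tooth section into a density map
#'
#' Applies the batch calibration line elementwise over formed-enamel pixels.
#' Pixels at or below `background_threshold` (grey 0 by convention) are
#' masked out as background.
#'
#' @param section A `tooth_section`.
#' @param calib A [calibration_params()] matching the section's batch.
#' @param background_threshold Grey values <= this are background.
#' @return A `density_map`: list with `densities` (matrix, NA outside the
#'   mask), `mask` (logical matrix), `pixel_size_mm`, `specimen_id`,
#'   `age_days`.
#' @export
calibrate_section <- function(section, calib, background_threshold = 0) {
  stopifnot(inherits(section, "tooth_section"),
            inherits(calib, "calibration_params"))
  if (!identical(as.integer(section$batch), as.integer(calib$batch_id))) {
    stop(sprintf("calibration batch %s does not match section batch %s",
                 calib$batch_id, section$batch), call. = FALSE)
  }
  mask <- section$pixels > background_threshold
  densities <- matrix(NA_real_, nrow(mask), ncol(mask))
  densities[mask] <- grey_to_density(section$pixels[mask], calib)
  structure(
    list(densities = densities, mask = mask,
         pixel_size_mm = section$pixel_size_mm,
         specimen_id = section$specimen_id, age_days = section$age_days),
    class = "density_map"
  )
}

read_grey_image <- function(path) {
  img <- tryCatch({
    if (grepl("\\.png$", path, ignore.case = TRUE)) {
      round(png::readPNG(path) * 65535)
    } else {
      tiff::readTIFF(path, as.is = TRUE)
    }
  }, error = function(e) {
    stop(sprintf("cannot read image '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (length(dim(img)) == 3L) img <- img[, , 1]
  if (max(img) <= 255 && !grepl("\\.png$", path, ignore.case = TRUE)) {
    warning(sprintf("'%s' looks 8-bit; promoting to 16-bit grey range",
                    basename(path)), call. = FALSE)
    img <- img * 257
  }
  storage.mode(img) <- "integer"
  img
}

#' Load a section series from a manifest
#'
#' Reads a CSV manifest (columns: id, age_days, batch, molar, worn,
#' filename) and the grayscale images it references. Rows whose image file
#' is missing are reported with a warning and skipped; negative ages are
#' accepted (first molars initiate prenatally).
#'
#' @param manifest_path Path to the manifest CSV.
#' @param image_dir Directory holding the images; defaults to the
#'   manifest's directory.
#' @return A list of `tooth_section` objects.
#' @export
load_manifest <- function(manifest_path, image_dir = dirname(manifest_path)) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  if (nrow(man) == 0) return(list())
  keep <- file.exists(file.path(image_dir, man$filename))
  if (any(!keep)) {
    warning(sprintf("skipping %d manifest row(s) with missing image files: %s",
                    sum(!keep),
                    paste(man$filename[!keep], collapse = ", ")),
            call. = FALSE)
  }
  man <- man[keep, , drop = FALSE]
  purrr::pmap(man, function(id, age_days, batch, molar, worn, filename, ...) {
    extra <- list(...)
    structure(
      list(specimen_id = as.character(id), age_days = age_days,
           batch = batch, molar = molar, worn = as.logical(worn),
           pixels = read_grey_image(file.path(image_dir, filename)),
           pixel_size_mm = extra$pixel_size_mm %||% 0.2),
      class = "tooth_section"
    )
  })
}
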