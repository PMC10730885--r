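#' Littmann-Bennett magnification scale factor
#'
#' Relative ocular magnification of an eye of axial length `axial_length`
#' versus the device's assumed eye.  With the Bennett scaling
#' `q = 0.01306 (AL - 1.82)`, the ratio reduces to
#' `(AL - 1.82) / (assumed_AL - 1.82)`; the leading constant cancels.
#' The corrected physical scan width is the nominal width times this factor.
#'
#' @param axial_length measured axial length, mm (> 1.82).
#' @param assumed_axial_length axial length assumed by the device, mm
#'   (default 24.46).
#' @return dimensionless scale factor, 1 at the assumed axial length.
#' @export
bennett_scale_factor <- function(axial_length, assumed_axial_length = 24.46) {
  if (any(axial_length <= 1.82) || any(assumed_axial_length <= 1.82))
    stop("axial lengths must exceed 1.82 mm")
  (axial_length - 1.82) / (assumed_axial_length - 1.82)
}

#' Scan geometry descriptor
#'
#' @param axial_length axial length of the eye, mm.
#' @param assumed_axial_length device-assumed axial length, mm.
#' @param nominal_scan_size nominal scan width, mm.
#' @param pixel_size nominal mm per pixel.
#' @return a `scan_geometry` list.
#' @export
scan_geometry <- function(axial_length, assumed_axial_length = 24.46,
                          nominal_scan_size = 3.0, pixel_size = 3 / 512) {
  stopifnot(axial_length > 15, axial_length < 27,
            assumed_axial_length > 1.82)
  structure(list(axial_length = axial_length,
                 assumed_axial_length = assumed_axial_length,
                 nominal_scan_size = nominal_scan_size,
                 pixel_size = pixel_size), class = "scan_geometry")
}

#' Magnification-correct and crop an en-face slab
#'
#' Applies the Littmann-Bennett correction as a metadata rescale (the pixel
#' grid is never resampled: the physical pixel size is multiplied by the
#' Bennett factor) and takes a centred crop of `crop_size_mm` - the common
#' analyzed extent.  The crop pixel count floors to a whole pixel; the
#' exact realized physical size is recorded in the result's metadata.
#'
#' @param image an [enface_image()].
#' @param geometry a [scan_geometry()].
#' @param crop_size_mm analyzed extent, default 2.7 mm.
#' @return corrected and cropped `enface_image` (with `crop_size_mm_exact`
#'   attached), or an object of class `eye_exclusion` (fields `eye_id`,
#'   `code`) when the corrected extent is smaller than the crop.
#' @export
correct_and_crop <- function(image, geometry, crop_size_mm = 2.7) {
  stopifnot(inherits(image, "enface_image"))
  f <- bennett_scale_factor(geometry$axial_length, geometry$assumed_axial_length)
  corrected_pixel <- image$pixel_size * f
  corrected_width <- nrow(image$pixels) * corrected_pixel
  # a shortfall of less than one pixel is a rounding artifact of an earlier
  # floor-to-pixel crop, not a genuinely small scan; keeps the crop idempotent
  if (corrected_width < crop_size_mm - corrected_pixel) {
    return(structure(list(eye_id = image$eye_id,
                          code = "corrected_extent_lt_crop",
                          corrected_width = corrected_width),
                     class = "eye_exclusion"))
  }
  k <- min(floor(crop_size_mm / corrected_pixel), nrow(image$pixels))
  out <- enface_image(center_crop(image$pixels, k), corrected_pixel,
                      image$modality, image$eye_id)
  out$crop_size_mm_exact <- k * corrected_pixel
  out$bennett_factor <- f
  out
}

#' Image-quality inclusion filter
#'
#' Keeps records whose device quality index strictly exceeds 7; every
#' exclusion is logged with a reason (`"quality_index_le_7"`, or
#' `"missing_quality_index"` when the index is absent).
#'
#' @param records data.frame with `eye_id` and `quality_index` columns.
#' @return list with `included` (data.frame) and `exclusions`
#'   (data.frame of `eye_id`, `reason`).
#' @export
quality_filter <- function(records) {
  stopifnot("quality_index" %in% names(records))
  qi <- records$quality_index
  reason <- ifelse(is.na(qi), "missing_quality_index",
                   ifelse(qi <= 7, "quality_index_le_7", NA_character_))
  excluded <- !is.na(reason)
  list(included = records[!excluded, , drop = FALSE],
       exclusions = data.frame(eye_id = records$eye_id[excluded],
                               reason = reason[excluded],
                               stringsAsFactors = FALSE))
}
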