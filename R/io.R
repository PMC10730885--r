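#' Write an en-face image to disk
#'
#' 16-bit grayscale TIFF by default (`{eye_id}_{modality}.tif`), or 8-bit
#' PNG with `format = "png"`.
#'
#' @param image an [enface_image()].
#' @param dir output directory (created if needed).
#' @param format `"tiff"` or `"png"`.
#' @return the file path, invisibly.
#' @export
write_enface <- function(image, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  stopifnot(inherits(image, "enface_image"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- if (is.na(image$eye_id)) "eye" else image$eye_id
  px <- pmin(pmax(image$pixels, 0), 1)
  path <- file.path(dir, sprintf("%s_%s.%s", id, image$modality,
                                 if (format == "tiff") "tif" else "png"))
  if (format == "tiff") tiff::writeTIFF(px, path, bits.per.sample = 16L)
  else png::writePNG(px, path)
  invisible(path)
}

#' Read an en-face image from disk
#'
#' Reads TIFF or PNG, converts to a grayscale matrix in `[0, 1]` (multi-
#' channel images are averaged), and attaches the supplied geometry.
#'
#' @param path image file.
#' @param pixel_size mm per pixel.
#' @param modality slab type.
#' @param eye_id identifier.
#' @return an [enface_image()].
#' @export
read_enface <- function(path, pixel_size,
                        modality = c("cc_slab", "superficial_slab"),
                        eye_id = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
        else if (ext == "png") png::readPNG(path)
        else stop("unsupported image format: ", ext)
  if (length(dim(px)) == 3) px <- apply(px, c(1, 2), mean)
  enface_image(px, pixel_size, match.arg(modality), eye_id)
}

#' Write scene ground truth as a JSON sidecar (plus void-mask TIFF)
#'
#' @param truth `SceneTruth` list from a simulator.
#' @param dir output directory.
#' @param eye_id identifier used in file names.
#' @return the JSON path, invisibly.
#' @export
write_truth <- function(truth, dir, eye_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scalar <- truth[!vapply(truth, is.matrix, TRUE)]
  jsonlite::write_json(scalar, file.path(dir, paste0(eye_id, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth$void_mask))
    tiff::writeTIFF(truth$void_mask + 0,
                    file.path(dir, paste0(eye_id, "_void_mask.tif")))
  invisible(file.path(dir, paste0(eye_id, "_truth.json")))
}

#' Write / read a cohort table as CSV
#'
#' UTF-8, dot decimal separator, one row per eye.
#'
#' @param cohort data.frame.
#' @param path CSV path.
#' @return the path (write) or the data.frame (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Write presets to a YAML config file
#'
#' @param presets named list of presets.
#' @param path YAML path.
#' @return the path, invisibly.
#' @export
write_presets_yaml <- function(presets, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(presets, path)
  invisible(path)
}

#' @rdname write_presets_yaml
#' @export
read_presets_yaml <- function(path) {
  presets <- yaml::read_yaml(path)
  lapply(presets, function(p) {
    for (f in c("void_param", "heterogeneity_param", "cv_floor",
                "achieved_ccfa", "achieved_cv"))
      if (is.null(p[[f]])) p[[f]] <- NA_real_
    validate_preset(p)
    p
  })
}
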