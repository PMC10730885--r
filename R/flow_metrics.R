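#' Phansalkar threshold parameters
#'
#' Parameters of the Phansalkar local adaptive threshold
#' `T = m (1 + p exp(-q m) + k (s/R - 1))`, where `m` and `s` are the mean
#' and (population) SD of the intensities in the square window of radius
#' `window_radius` around each pixel.  Defaults follow the original method
#' for low-contrast images: p = 2, q = 10, k = 0.25, R = 0.5, and a window
#' radius of 4 px (~23 um at the default scale, on the order of
#' intercapillary distance).
#'
#' @param window_radius window radius in pixels (>= 1).
#' @param p,q,k,R dimensionless threshold constants.
#' @return a `phansalkar_params` list.
#' @export
phansalkar_params <- function(window_radius = 4L, p = 2.0, q = 10.0,
                              k = 0.25, R = 0.5) {
  stopifnot(window_radius >= 1, R > 0, k > 0)
  structure(list(window_radius = as.integer(window_radius),
                 p = p, q = q, k = k, R = R),
            class = "phansalkar_params")
}

check_normalized <- function(px) {
  if (min(px) < 0 || max(px) > 1)
    stop("image is not normalized to [0, 1]; rescale intensities first")
}

#' Per-pixel Phansalkar threshold map
#'
#' Local window statistics use reflect padding at the borders, so a
#' constant image yields a constant threshold map.
#'
#' @param image [enface_image()] or numeric matrix in `[0, 1]`.
#' @param params [phansalkar_params()].
#' @return numeric matrix of thresholds, same shape as the image.
#' @export
phansalkar_threshold <- function(image, params = phansalkar_params()) {
  px <- as_pixels(image)
  check_normalized(px)
  ms <- box_mean_sd(px, params$window_radius)
  ms$mean * (1 + params$p * exp(-params$q * ms$mean) +
               params$k * (ms$sd / params$R - 1))
}

#' Binarize a choriocapillaris slab into a flow map
#'
#' Flow polarity is fixed: pixels strictly brighter than their local
#' Phansalkar threshold are flow.
#'
#' @inheritParams phansalkar_threshold
#' @return a `binary_flow_map`: list with logical `mask` (`TRUE` = flow),
#'   `pixel_size` and `eye_id`.
#' @export
binarize_flow <- function(image, params = phansalkar_params()) {
  px <- as_pixels(image)
  thr <- phansalkar_threshold(image, params)
  structure(list(mask = px > thr,
                 pixel_size = if (inherits(image, "enface_image"))
                   image$pixel_size else NA_real_,
                 eye_id = if (inherits(image, "enface_image"))
                   image$eye_id else NA_character_),
            class = "binary_flow_map")
}

as_mask <- function(mask) {
  if (inherits(mask, "binary_flow_map")) mask$mask
  else if (is.matrix(mask)) mask > 0
  else stop("expected a binary_flow_map or a matrix")
}

#' Choriocapillaris flow area (CCFA) ratio
#'
#' Percentage of the analyzed area classified as flow signal:
#' `100 * flow pixels / total pixels`.
#'
#' @param mask a `binary_flow_map` or logical matrix.
#' @return percent in `[0, 100]`.
#' @export
ccfa_ratio <- function(mask) {
  m <- as_mask(mask)
  if (length(m) == 0) stop("empty mask")
  100 * sum(m) / length(m)
}

#' Coefficient of variation of the CCFA ratio over a tile grid
#'
#' Splits the binarized image into a `grid x grid` array of equal square
#' tiles (default 18 x 18, i.e. 324 tiles of ~150 um on the 2.7 mm
#' analyzed extent), computes each tile's flow fraction, and returns their
#' coefficient of variation: sample (n-1) standard deviation divided by
#' the mean.  The mask is first trimmed (centred) to the largest multiple
#' of `grid`; the trim is recorded.
#'
#' @param mask a `binary_flow_map` or logical matrix, side >= `grid`.
#' @param grid tiles per side (default 18).
#' @return list with `tile_ratios` (row-major, length `grid^2`), `cv`
#'   (`NA` with `reason = "zero_mean_flow"` when no tile contains flow),
#'   `grid`, `tile_px` and `trim_px`.
#' @export
cv_of_ccfa <- function(mask, grid = 18L) {
  m <- as_mask(mask)
  side <- min(dim(m))
  if (side < grid) stop("mask side must be >= grid")
  t_px <- side %/% grid
  used <- t_px * grid
  m <- center_crop(m, used)
  # per-tile sums: collapse rows then columns in t_px blocks
  rowblk <- rowsum(m + 0, rep(seq_len(grid), each = t_px))
  tile <- t(rowsum(t(rowblk), rep(seq_len(grid), each = t_px)))
  ratios <- as.numeric(t(tile)) / t_px^2   # row-major order
  mu <- mean(ratios)
  if (mu == 0) {
    return(list(tile_ratios = ratios, cv = NA_real_,
                reason = "zero_mean_flow", grid = grid,
                tile_px = t_px, trim_px = side - used))
  }
  list(tile_ratios = ratios, cv = sd(ratios) / mu, grid = grid,
       tile_px = t_px, trim_px = side - used)
}

#' Two-threshold impaired-flow classifier
#'
#' An eye is classified as having impaired choriocapillaris flow when its
#' CCFA ratio is strictly below the first cutoff AND its CV of the CCFA
#' ratio is at or above the second (defaults 65.9% and 0.140, the published
#' Youden cutoffs).
#'
#' @param ccfa_ratio percent.
#' @param cv dimensionless CV of the CCFA ratio.
#' @param cutoffs length-2 numeric: CCFA cutoff (strict `<`) and CV cutoff
#'   (`>=`).
#' @return logical vector.
#' @export
classify_impaired <- function(ccfa_ratio, cv, cutoffs = c(65.9, 0.140)) {
  ccfa_ratio < cutoffs[1] & cv >= cutoffs[2]
}
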