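#' Construct an en-face image object
#'
#' Lightweight container for a grayscale en-face OCTA slab: a square pixel
#' matrix with intensities in `[0, 1]`, an isotropic physical pixel size and
#' the nominal scan size.
#'
#' @param pixels numeric matrix in `[0, 1]`.
#' @param pixel_size mm per pixel.
#' @param modality `"cc_slab"` (choriocapillaris) or `"superficial_slab"`.
#' @param eye_id optional identifier carried through the pipeline.
#' @return an `enface_image` object.
#' @export
enface_image <- function(pixels, pixel_size,
                         modality = c("cc_slab", "superficial_slab"),
                         eye_id = NA_character_) {
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels), pixel_size > 0)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 nominal_scan_size = nrow(pixels) * pixel_size,
                 modality = match.arg(modality), eye_id = eye_id),
            class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image %s: %d x %d px, %.4f mm/px, %.2f mm>\n",
              x$modality, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              x$nominal_scan_size))
  invisible(x)
}

as_pixels <- function(image) {
  if (inherits(image, "enface_image")) image$pixels
  else if (is.matrix(image)) image
  else stop("expected an enface_image or a numeric matrix")
}

#' Multiplicative log-normal speckle
#'
#' Multiplies each pixel by an i.i.d. log-normal factor with unit mean
#' (`meanlog = -sigma^2/2`, `sdlog = sigma`), the standard first-order
#' model for OCT speckle.  `sigma = 0` is the identity.  No clipping is
#' applied here; callers clip to `[0, 1]` after composing the scene.
#'
#' @param image `enface_image` or matrix.
#' @param sigma log-scale SD of the speckle, `>= 0`.
#' @param seed RNG seed.
#' @return object of the same type as `image`.
#' @export
add_speckle <- function(image, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  px <- as_pixels(image)
  if (sigma == 0) return(image)
  noisy <- with_seed(seed, {
    px * matrix(stats::rlnorm(length(px), meanlog = -sigma^2 / 2, sdlog = sigma),
                nrow(px), ncol(px))
  })
  if (inherits(image, "enface_image")) { image$pixels <- noisy; image } else noisy
}

# Smooth positive heterogeneity field: exponentiated Gaussian-blurred white
# noise with correlation scale `corr_mm`, normalized to mean 1.  `h` is the
# log-amplitude; h = 0 gives the constant field 1.
heterogeneity_field <- function(side_px, pixel_size, h, corr_mm = 0.3) {
  if (h == 0) return(matrix(1, side_px, side_px))
  sigma_px <- corr_mm / pixel_size / 2
  # the field only has power at scales >> pixel: synthesize on a coarse
  # grid and upsample bilinearly
  dec <- 8L
  side_c <- as.integer(ceiling(side_px / dec)) + 4L
  g <- matrix(rnorm(side_c^2), side_c, side_c)
  g <- EBImage::gblur(g, sigma = sigma_px / dec)
  g <- matrix(EBImage::resize(g, w = side_px, h = side_px), side_px, side_px)
  g <- (g - mean(g)) / sd(g)
  f <- exp(h * g)
  f / mean(f)
}

# Baseline choriocapillaris texture: a jittered hexagonal lattice of
# lobules (domain diameter ~200-250 um); intensity falls off mildly from
# lobule centre to boundary.  Deterministic given the RNG state.
lobule_texture <- function(side_px, pixel_size, lobule_diameter_um = 225,
                           base_hi = 0.78, base_lo = 0.62) {
  s <- lobule_diameter_um / (pixel_size * 1000)   # lattice spacing, px
  ys <- seq(-s, side_px + s, by = s * sqrt(3) / 2)
  centers <- do.call(rbind, lapply(seq_along(ys), function(i) {
    xo <- if (i %% 2 == 0) s / 2 else 0
    xs <- seq(-s, side_px + s, by = s) + xo
    cbind(xs, ys[i])
  }))
  centers <- centers + matrix(rnorm(length(centers), 0, 0.10 * s), ncol = 2)
  keep <- centers[, 1] > -s & centers[, 1] < side_px + s &
          centers[, 2] > -s & centers[, 2] < side_px + s
  centers <- centers[keep, , drop = FALSE]
  # distance to nearest lobule centre via distance transform
  seedimg <- matrix(1, side_px, side_px)
  ij <- cbind(pmin(pmax(round(centers[, 2]), 1), side_px),
              pmin(pmax(round(centers[, 1]), 1), side_px))
  seedimg[ij] <- 0
  d <- EBImage::distmap(seedimg)
  d <- pmin(as.numeric(d) / (0.62 * s), 1)
  matrix(base_hi - (base_hi - base_lo) * d^2, side_px, side_px)
}

#' Simulate a choriocapillaris en-face slab with flow voids
#'
#' Renders a bright lobular baseline texture (jittered hexagonal lattice of
#' capillary lobules) and stamps dark flow voids - unions of random
#' ellipses - until the void area reaches `void_param` of the frame.  Void
#' centres are modulated by a smooth spatial heterogeneity field of
#' log-amplitude `heterogeneity_param`, so the *global* void coverage is
#' controlled independently of its *spatial clustering*.  Multiplicative
#' speckle is applied last, then intensities are clipped to `[0, 1]`.
#'
#' @param preset a `GroupPreset` with `void_param` (target void coverage
#'   fraction in `[0, 1]`) and `heterogeneity_param` set; see
#'   [calibrate_preset()].
#' @param side_px canvas side (>= 128, default 512).
#' @param pixel_size mm per pixel (default 3 mm / `side_px`).
#' @param seed RNG seed; identical seeds give identical pixel grids.
#' @param noise apply speckle (default TRUE, sigma 0.18).
#' @param speckle_sigma speckle log-SD.
#' @param void_minor_um range (um) of the void ellipse minor axis; most
#'   voids are at the intercapillary scale, which keeps the tile-CV floor
#'   low.
#' @param void_aspect range of the ellipse aspect ratio (major / minor).
#' @param void_large_um minor-axis range (um) of the occasional large
#'   confluent void.
#' @param p_large probability that a void is drawn from the large class.
#' @param eye_id identifier carried into the image metadata.
#' @return list with `image` (an [enface_image()]) and `truth`
#'   (`SceneTruth`: exact `true_flow_fraction`, `void_mask`,
#'   `heterogeneity_field`, `lobule_diameter_um`).
#' @export
simulate_cc_slab <- function(preset, side_px = 512L, pixel_size = 3 / side_px,
                             seed = 1L, noise = TRUE, speckle_sigma = 0.18,
                             void_minor_um = c(18, 26),
                             void_aspect = c(1, 1.6),
                             void_large_um = c(40, 80), p_large = 0.015,
                             eye_id = NA_character_) {
  if (side_px < 128) stop("side_px must be >= 128")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  v <- preset$void_param
  if (is.na(v)) stop("preset$void_param is not set; run calibrate_preset() first")
  if (v < 0 || v > 1) stop("void_param must lie in [0, 1]")
  h <- preset$heterogeneity_param
  if (is.na(h)) h <- 0
  um <- pixel_size * 1000
  out <- with_seed(seed, {
    tex <- lobule_texture(side_px, pixel_size)
    fld <- heterogeneity_field(side_px, pixel_size, h)
    if (v > 0) {
      target_px <- round(min(v, 0.97) * side_px^2)
      st <- .cf_stamp_voids(side_px, side_px, target_px, fld / max(fld),
                            void_minor_um[1] / 2 / um, void_minor_um[2] / 2 / um,
                            void_large_um[1] / 2 / um, void_large_um[2] / 2 / um,
                            p_large, void_aspect[1], void_aspect[2], 400000L)
      voidmask <- st$mask == 1L
    } else {
      voidmask <- matrix(FALSE, side_px, side_px)
    }
    img <- tex * ifelse(voidmask, 0.12, 1)
    if (noise) img <- add_speckle(img, speckle_sigma,
                                  seed = sample.int(2^30, 1))
    img[img < 0] <- 0; img[img > 1] <- 1
    list(img = img, voidmask = voidmask, fld = fld)
  })
  list(
    image = enface_image(out$img, pixel_size, "cc_slab", eye_id),
    truth = list(
      true_flow_fraction = 1 - sum(out$voidmask) / length(out$voidmask),
      void_mask = out$voidmask,
      heterogeneity_field = out$fld,
      lobule_diameter_um = 225
    )
  )
}

#' Simulate a superficial-plexus slab with known centerline length
#'
#' Grows a branching, collision-avoiding vessel network on the pixel grid
#' until the total centerline length per unit area reaches `target_vld`.
#' Growth proceeds in 8-neighbour steps, so the exact generated length is
#' known in the 8-connected chain metric (1 per orthogonal step, sqrt(2)
#' per diagonal step) - the same metric the skeleton length estimator
#' uses.  Centerlines are dilated to capillary calibre (~3 px), rendered
#' bright on a dark background, and speckled.
#'
#' @param target_vld target vessel length density in mm/mm^2, in `(0, 40]`.
#' @param side_px canvas side (default 512).
#' @param pixel_size mm per pixel (default 3 mm / `side_px`).
#' @param seed RNG seed.
#' @param noise apply speckle (default TRUE, sigma 0.20).
#' @param speckle_sigma speckle log-SD.
#' @param eye_id identifier carried into the image metadata.
#' @return list with `image` ([enface_image()]) and `truth`
#'   (`vessel_centerline_length_mm`, `vld` = length / area,
#'   `centerline_mask`).
#' @export
simulate_superficial_slab <- function(target_vld, side_px = 512L,
                                      pixel_size = 3 / side_px, seed = 1L,
                                      noise = TRUE, speckle_sigma = 0.20,
                                      eye_id = NA_character_) {
  if (!is.finite(target_vld) || target_vld <= 0 || target_vld > 40)
    stop("target_vld must lie in (0, 40]")
  if (side_px <= 0 || pixel_size <= 0) stop("dimensions must be positive")
  area_mm2 <- (side_px * pixel_size)^2
  target_len_px <- target_vld * area_mm2 / pixel_size
  out <- with_seed(seed, {
    net <- .cf_grow_network(side_px, side_px, target_len_px,
                            jitter = 0.18, branch_p = 0.08, dmin = 2L,
                            look = 3L, max_tips = 400L, n_seed0 = 25L,
                            max_steps = as.integer(min(2^31 - 1, target_len_px * 60)))
    if (!net$reached)
      stop(sprintf("unreachable target VLD %.2f: image saturated at %.2f mm/mm^2",
                   target_vld, net$length_px * pixel_size / area_mm2))
    centerline <- net$centerline == 1L
    vessels <- EBImage::dilate(centerline + 0,
                               EBImage::makeBrush(3, shape = "box")) > 0
    img <- 0.12 + 0.73 * vessels
    if (noise) img <- add_speckle(img, speckle_sigma, seed = sample.int(2^30, 1))
    img[img < 0] <- 0; img[img > 1] <- 1
    list(img = img, centerline = centerline, len_px = net$length_px)
  })
  list(
    image = enface_image(out$img, pixel_size, "superficial_slab", eye_id),
    truth = list(
      vessel_centerline_length_mm = out$len_px * pixel_size,
      vld = out$len_px * pixel_size / area_mm2,
      centerline_mask = out$centerline
    )
  )
}
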