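#' Measure one simulated choriocapillaris eye end to end
#'
#' Runs the full measurement chain on one synthetic eye: simulate the
#' choriocapillaris slab, apply the Littmann-Bennett correction and the
#' 2.7 mm centred crop, binarize with the Phansalkar threshold, and
#' compute the CCFA ratio and its tile CV.
#'
#' @param preset `GroupPreset` with simulator controls set.
#' @param seed RNG seed for the simulated eye.
#' @param axial_length axial length used for the magnification correction
#'   (defaults to the device-assumed eye, i.e. factor 1).
#' @param side_px,pixel_size canvas geometry.
#' @param noise apply speckle.
#' @param params [phansalkar_params()].
#' @param crop_size_mm analyzed extent (default 2.7).
#' @param pixel_size mm per pixel (default 3 mm / `side_px`).
#' @return list with `ccfa`, `cv`, `true_flow_fraction`, or an exclusion
#'   code when the corrected extent cannot cover the crop.
#' @export
measure_cc_eye <- function(preset, seed, axial_length = 24.46,
                           side_px = 512L, pixel_size = 3 / side_px,
                           noise = TRUE, params = phansalkar_params(),
                           crop_size_mm = 2.7) {
  sim <- simulate_cc_slab(preset, side_px, pixel_size, seed, noise)
  geom <- scan_geometry(axial_length, nominal_scan_size = side_px * pixel_size,
                        pixel_size = pixel_size)
  img <- correct_and_crop(sim$image, geom, crop_size_mm)
  if (inherits(img, "eye_exclusion"))
    return(list(ccfa = NA_real_, cv = NA_real_, excluded = img$code))
  bf <- binarize_flow(img, params)
  cvres <- cv_of_ccfa(bf)
  list(ccfa = ccfa_ratio(bf), cv = cvres$cv,
       true_flow_fraction = sim$truth$true_flow_fraction, excluded = NULL)
}

# Map a calibrated group preset to one eye's simulator controls.
# CCFA: the stamped void coverage shifts one-for-one with the target CCFA
# (percentage points / 100), anchored at the calibrated group mean.
# CV: under the variance decomposition cv^2 = floor^2 + (c h)^2, the
# calibrated anchor fixes c, and the eye's heterogeneity follows by
# inversion; targets at or below the floor map to h = 0.
eye_preset <- function(preset, ccfa_target, cv_target) {
  ep <- preset
  ep$void_param <- min(max(
    preset$void_param + (preset$target_ccfa_mean - ccfa_target) / 100, 0), 0.97)
  fl <- preset$cv_floor
  anchor <- preset$achieved_cv
  if (!is.na(fl) && !is.na(anchor) && anchor > fl) {
    num <- sqrt(max(cv_target^2 - fl^2, 0))
    den <- sqrt(anchor^2 - fl^2)
    ep$heterogeneity_param <- preset$heterogeneity_param * num / den
  }
  ep
}

#' Run the image pipeline over a generated cohort
#'
#' For every eye: renders the choriocapillaris slab from the eye's
#' calibrated per-eye simulator controls and measures CCFA ratio and tile
#' CV through the full preprocess + binarization chain; renders the
#' superficial slab at the eye's VLD target and estimates VLD by
#' skeletonization; classifies impaired flow from the measured values.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param presets calibrated presets (see [calibrate_preset()]).
#' @param side_px,pixel_size canvas geometry.
#' @param noise apply speckle.
#' @param measure_vld also render/measure the superficial slab
#'   (default TRUE; skipping it halves the runtime when only
#'   choriocapillaris metrics are needed).
#' @param use_axial_length use each eye's axial length for the
#'   magnification correction (default TRUE).
#' @return `cohort` with measured columns `ccfa_ratio`, `cv_ccfa`, `vld`
#'   and `impaired` appended.
#' @export
run_cohort_images <- function(cohort, presets, side_px = 512L,
                              pixel_size = 3 / side_px, noise = TRUE,
                              measure_vld = TRUE, use_axial_length = TRUE) {
  n <- nrow(cohort)
  ccfa <- cvv <- vldv <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pr <- presets[[cohort$group[i]]]
    ep <- eye_preset(pr, cohort$ccfa_target[i], cohort$cv_target[i])
    al <- if (use_axial_length) cohort$axial_length[i] else 24.46
    m <- measure_cc_eye(ep, seed = cohort$eye_seed[i] + 1,
                        axial_length = al, side_px = side_px,
                        pixel_size = pixel_size, noise = noise)
    ccfa[i] <- m$ccfa; cvv[i] <- m$cv
    if (measure_vld) {
      sup <- simulate_superficial_slab(cohort$vld_target[i], side_px,
                                       pixel_size,
                                       seed = cohort$eye_seed[i] + 2,
                                       noise = noise)
      vldv[i] <- vld(sup$image)$vld
    }
  }
  cohort$ccfa_ratio <- ccfa
  cohort$cv_ccfa <- cvv
  if (measure_vld) cohort$vld <- vldv
  cohort$impaired <- classify_impaired(ccfa, cvv)
  cohort
}
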