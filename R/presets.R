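#' Default group presets for the synthetic cohort
#'
#' One preset per study group (healthy control, diabetes without retinopathy,
#' diabetic retinopathy).  Targets are the group means and SDs of the
#' published flow and outer-retina statistics that the generator is asked to
#' reproduce: CCFA ratio (%), CV of the CCFA ratio, superficial vessel
#' length density (mm/mm^2), photoreceptor outer segment length (um) and
#' RPE volume (stored with its reported unit string, "um^3").  The
#' `severity_loading_*` entries wire every channel to a single latent
#' severity factor so that cross-channel correlations match the published
#' ones (see the methods vignette for the closed-form derivation).
#' `void_param` and `heterogeneity_param` are simulator controls and are set
#' by [calibrate_preset()]; they default to `NA`.
#'
#' The RPE volume of the diabetic-without-retinopathy group has no
#' reference value; the preset interpolates 0.39 +/- 0.025 between the two
#' reported groups.
#'
#' @return named list of `GroupPreset` lists, one per group.
#' @export
default_presets <- function() {
  base <- list(
    # loadings on the shared latent severity factor (z > 0 = healthier)
    severity_loading_ccfa = 0.700,
    severity_loading_vld  = 0.500,
    severity_loading_cv   = -0.654,
    severity_loading_pros = 0.204,
    severity_loading_rpe  = -0.497,
    void_param = NA_real_, heterogeneity_param = NA_real_,
    cv_floor = NA_real_, achieved_ccfa = NA_real_, achieved_cv = NA_real_
  )
  p <- list(
    control = c(list(
      group = "control",
      target_ccfa_mean = 69.1, target_ccfa_sd = 3.8,
      target_cv_mean = 0.124, target_cv_sd = 0.019,
      target_vld_mean = 21.2, target_vld_sd = 0.7,
      pros_mean = 64.5, pros_sd = 5.2,
      rpe_mean = 0.38, rpe_sd = 0.02,
      age_mean = 44.8, age_sd = 12.1, age_range = c(27, 61),
      male_prop = 2 / 12,
      bcva_mean = -0.17, bcva_sd = 0.03,
      crt_mean = 264, crt_sd = 17, crt_range = c(236, 289)
    ), base),
    dm_no_dr = c(list(
      group = "dm_no_dr",
      target_ccfa_mean = 62.7, target_ccfa_sd = 6.9,
      target_cv_mean = 0.150, target_cv_sd = 0.028,
      target_vld_mean = 20.7, target_vld_sd = 0.7,
      pros_mean = 57.0, pros_sd = 6.0,
      rpe_mean = 0.39, rpe_sd = 0.025,
      age_mean = 50.0, age_sd = 5.8, age_range = c(37, 60),
      male_prop = 8 / 15,
      bcva_mean = -0.11, bcva_sd = 0.08,
      crt_mean = 269, crt_sd = 10, crt_range = c(248, 285)
    ), base),
    dr = c(list(
      group = "dr",
      target_ccfa_mean = 58.4, target_ccfa_sd = 6.1,
      target_cv_mean = 0.174, target_cv_sd = 0.035,
      target_vld_mean = 18.2, target_vld_sd = 1.7,
      pros_mean = 56.7, pros_sd = 6.0,
      rpe_mean = 0.40, rpe_sd = 0.03,
      age_mean = 52.5, age_sd = 4.9, age_range = c(42, 60),
      male_prop = 15 / 18,
      bcva_mean = -0.12, bcva_sd = 0.05,
      crt_mean = 264, crt_sd = 24, crt_range = c(226, 304)
    ), base)
  )
  for (g in names(p)) validate_preset(p[[g]])
  p
}

#' Validate a group preset
#'
#' Checks SD non-negativity and physical ranges; raises a configuration
#' error naming the offending field.
#'
#' @param preset a `GroupPreset` list.
#' @return the preset, invisibly.
#' @export
validate_preset <- function(preset) {
  sds <- grep("_sd$", names(preset), value = TRUE)
  for (f in sds) {
    if (!is.na(preset[[f]]) && preset[[f]] < 0)
      stop("configuration error: negative SD in field '", f, "'", call. = FALSE)
  }
  if (preset$target_ccfa_mean < 0 || preset$target_ccfa_mean > 100)
    stop("configuration error: 'target_ccfa_mean' outside [0, 100]", call. = FALSE)
  if (preset$target_cv_mean < 0)
    stop("configuration error: 'target_cv_mean' must be nonnegative", call. = FALSE)
  if (preset$target_vld_mean <= 0 || preset$target_vld_mean > 40)
    stop("configuration error: 'target_vld_mean' outside (0, 40]", call. = FALSE)
  if (!is.na(preset$void_param) &&
      (preset$void_param < 0 || preset$void_param > 1))
    stop("configuration error: 'void_param' outside [0, 1]", call. = FALSE)
  invisible(preset)
}

#' Default systemic-association preset
#'
#' Conditional exceedance model for the systemic exposures: for each binary
#' exposure indicator, log-odds of exceeding its clinical cutoff =
#' `base_logit + age_coef * (age - 50) + log(or) * impaired`.  The default
#' odds ratios are the published age-adjusted ones (HbA1c >= 7.0%: 4.992;
#' systolic BP >= 135 mmHg: 5.572; and the remaining lipid/pressure
#' exposures of the risk-factor table).  Continuous lab values are then
#' drawn from truncated normals on the matching side of each cutoff.
#'
#' @return named list of per-exposure association parameters.
#' @export
default_assoc_preset <- function() {
  list(
    impaired_base_logit = 0.0, impaired_age_coef = 0.05,
    exposures = list(
      hba1c_ge_7    = list(or = 4.992, base_logit = qlogis(0.25), age_coef = 0.01,
                           cutoff = 7.0,  ge = TRUE,
                           lo = list(mean = 6.2, sd = 0.45), hi = list(mean = 8.1, sd = 0.9)),
      sbp_ge_135    = list(or = 5.572, base_logit = qlogis(0.25), age_coef = 0.03,
                           cutoff = 135,  ge = TRUE,
                           lo = list(mean = 121, sd = 8), hi = list(mean = 144, sd = 8)),
      dbp_ge_85     = list(or = 1.207, base_logit = qlogis(0.20), age_coef = 0.02,
                           cutoff = 85,   ge = TRUE,
                           lo = list(mean = 75, sd = 6),  hi = list(mean = 91, sd = 5)),
      hdl_lt_40     = list(or = 1.759, base_logit = qlogis(0.10), age_coef = 0.00,
                           cutoff = 40,   ge = FALSE,
                           lo = list(mean = 34, sd = 3),  hi = list(mean = 56, sd = 10)),
      ldl_ge_140    = list(or = 1.148, base_logit = qlogis(0.25), age_coef = 0.01,
                           cutoff = 140,  ge = TRUE,
                           lo = list(mean = 112, sd = 16), hi = list(mean = 155, sd = 12)),
      tg_ge_150     = list(or = 0.946, base_logit = qlogis(0.30), age_coef = 0.01,
                           cutoff = 150,  ge = TRUE,
                           lo = list(mean = 105, sd = 25), hi = list(mean = 195, sd = 40)),
      tc_ge_220     = list(or = 0.689, base_logit = qlogis(0.25), age_coef = 0.01,
                           cutoff = 220,  ge = TRUE,
                           lo = list(mean = 190, sd = 18), hi = list(mean = 238, sd = 14))
    )
  )
}
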