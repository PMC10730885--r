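# Truncated-normal draw by resampling (preserves the mean approximately
# while enforcing hard physical ranges).
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf, max_tries = 1000L) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  for (i in seq_len(max_tries)) {
    bad <- out < lo | out > hi
    if (!any(bad)) return(out)
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  stop("truncated-normal resampling failed to converge")
}

# One channel tied to the latent severity z: mean + sd * (l*z + sqrt(1-l^2)*e).
severity_channel <- function(z, mean, sd, loading, lo = -Inf, hi = Inf) {
  stopifnot(abs(loading) <= 1)
  x <- mean + sd * (loading * z + sqrt(1 - loading^2) * rnorm(length(z)))
  # enforce range by redrawing the independent residual only
  for (i in seq_len(1000L)) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- mean + sd * (loading * z[bad] + sqrt(1 - loading^2) * rnorm(sum(bad)))
  }
  x[x < lo] <- lo; x[x > hi] <- hi
  x
}

#' Generate a synthetic three-group cohort of eyes
#'
#' Draws one row per eye with demographics, inclusion-criterion variables,
#' outer-retina measurements and the per-eye *targets* for the
#' image-derived channels (CCFA ratio, CV of the CCFA ratio, vessel length
#' density).  All continuous channels within an eye load on a single latent
#' severity factor `z` so that cross-channel correlations reproduce the
#' published ones; image targets are later passed to the OCTA simulator,
#' which renders images whose measured statistics match them.
#'
#' Eyes violating the inclusion criteria (logMAR BCVA < 0.05, axial length
#' < 27 mm, positive measurements) are resampled, never emitted.  Each eye
#' uses its own RNG seed derived from `base_seed` and the eye index
#' (`(base_seed mod 21000) * 1e5 + 3 * index`), so a fixed configuration
#' reproduces the identical table while cohorts with different base seeds
#' share no random draws; the two trailing offsets of each eye's seed are
#' reserved for its choriocapillaris and superficial image renders.
#'
#' @param config list with `n_per_group` (length-3 integer, default
#'   `c(12, 15, 18)` for control / diabetes-no-DR / DR), `base_seed`
#'   (non-negative integer) and optionally `presets`
#'   (default [default_presets()]) and `assoc` (default
#'   [default_assoc_preset()]).
#' @param fill_systemic draw systemic labs via [sample_systemic()], using the
#'   two-threshold classification of the eye's target flow statistics as the
#'   impaired-flow flag (default `TRUE`).
#' @return data.frame of `EyeRecord` rows.
#' @export
generate_cohort <- function(config = list(), fill_systemic = TRUE) {
  n_per_group <- config$n_per_group %||% c(12L, 15L, 18L)
  base_seed <- config$base_seed %||% 1L
  presets <- config$presets %||% default_presets()
  assoc <- config$assoc %||% default_assoc_preset()
  stopifnot(length(n_per_group) == 3L, all(n_per_group >= 2L), base_seed >= 0)
  for (p in presets) validate_preset(p)
  groups <- c("control", "dm_no_dr", "dr")
  rows <- vector("list", sum(n_per_group))
  idx <- 0L
  for (gi in seq_along(groups)) {
    pr <- presets[[groups[gi]]]
    for (k in seq_len(n_per_group[gi])) {
      idx <- idx + 1L
      eye_seed <- (base_seed %% 21000) * 100000 + 3L * idx
      rows[[idx]] <- with_seed(eye_seed, {
        z <- rnorm(1)
        age <- rnorm_trunc(1, pr$age_mean, pr$age_sd, pr$age_range[1], pr$age_range[2])
        data.frame(
          eye_id = sprintf("eye_%03d", idx),
          group = groups[gi],
          eye_seed = eye_seed,
          latent_z = z,
          age = age,
          sex = if (runif(1) < pr$male_prop) "male" else "female",
          bcva_logmar = rnorm_trunc(1, pr$bcva_mean, pr$bcva_sd, -0.30, 0.049),
          axial_length = rnorm_trunc(1, 24.2, 0.7, 22.5, 26.5),
          quality_index = sample(8:10, 1, prob = c(0.3, 0.4, 0.3)),
          central_retinal_thickness =
            rnorm_trunc(1, pr$crt_mean, pr$crt_sd, pr$crt_range[1], pr$crt_range[2]),
          ccfa_target = severity_channel(z, pr$target_ccfa_mean, pr$target_ccfa_sd,
                                         pr$severity_loading_ccfa, 1, 99.9),
          cv_target = severity_channel(z, pr$target_cv_mean, pr$target_cv_sd,
                                       pr$severity_loading_cv, 1e-4, 1),
          vld_target = severity_channel(z, pr$target_vld_mean, pr$target_vld_sd,
                                        pr$severity_loading_vld, 5, 40),
          pros_length = severity_channel(z, pr$pros_mean, pr$pros_sd,
                                         pr$severity_loading_pros, 20, 120),
          rpe_volume = severity_channel(z, pr$rpe_mean, pr$rpe_sd,
                                        pr$severity_loading_rpe, 0.2, 0.6),
          rpe_volume_unit = "um^3 (as reported)",
          stringsAsFactors = FALSE
        )
      })
    }
  }
  cohort <- do.call(rbind, rows)
  if (fill_systemic) {
    impaired <- classify_impaired(cohort$ccfa_target, cohort$cv_target)
    cohort <- sample_systemic(cohort, impaired, assoc,
                              seed = (base_seed %% 21000) * 100000 + 99999)
  }
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fill systemic laboratory values conditional on impaired-flow status
#'
#' For each exposure in the association preset, draws a binary exceedance
#' indicator from the logistic model
#' `logit P = base_logit + age_coef * (age - 50) + log(or) * impaired`,
#' then draws the continuous value from a truncated normal on the matching
#' side of the clinical cutoff.  Derived lipid quantities
#' (non-HDL cholesterol, LDL/HDL ratio) are computed from the drawn values.
#'
#' @param records data.frame with at least an `age` column.
#' @param impaired logical vector, the impaired-flow flag per row.
#' @param assoc association preset, see [default_assoc_preset()].
#' @param seed RNG seed.
#' @return `records` with lab columns and `*_ge_*`/`*_lt_*` indicators added.
#' @export
sample_systemic <- function(records, impaired, assoc = default_assoc_preset(),
                            seed = 1L) {
  stopifnot(nrow(records) == length(impaired))
  n <- nrow(records)
  cont_name <- c(hba1c_ge_7 = "hba1c", sbp_ge_135 = "systolic_bp",
                 dbp_ge_85 = "diastolic_bp", hdl_lt_40 = "hdl_c",
                 ldl_ge_140 = "ldl_c", tg_ge_150 = "triglyceride",
                 tc_ge_220 = "total_cholesterol")
  with_seed(seed, {
    for (ex in names(assoc$exposures)) {
      a <- assoc$exposures[[ex]]
      eta <- a$base_logit + a$age_coef * (records$age - 50) + log(a$or) * impaired
      ind <- rbinom(n, 1L, plogis(eta))
      exceed_side <- if (a$ge) "hi" else "lo"   # side of the cutoff that flags exposure
      other_side <- if (a$ge) "lo" else "hi"
      val <- numeric(n)
      for (s in c(TRUE, FALSE)) {
        sel <- (ind == 1L) == s
        if (!any(sel)) next
        d <- if (s) a[[exceed_side]] else a[[other_side]]
        bounds <- if (xor(s, !a$ge)) c(a$cutoff, Inf) else c(1e-6, a$cutoff - 1e-9)
        val[sel] <- rnorm_trunc(sum(sel), d$mean, d$sd, bounds[1], bounds[2])
      }
      records[[ex]] <- ind
      records[[cont_name[[ex]]]] <- val
    }
    records$non_hdl_c <- records$total_cholesterol - records$hdl_c
    records$non_hdl_c[records$non_hdl_c <= 0] <-
      records$total_cholesterol[records$non_hdl_c <= 0] * 0.5
    records$nonhdl_ge_170 <- as.integer(records$non_hdl_c >= 170)
    records$ldl_hdl_ge_2.5 <- as.integer(records$ldl_c / records$hdl_c >= 2.5)
    records$impaired_truth <- as.logical(impaired)
    records
  })
}

#' Simulate a tabular cohort for systemic-association recovery
#'
#' Generates `n` eyes with an age covariate, an age-dependent impaired-flow
#' status, and systemic labs from [sample_systemic()].  Used to check that
#' age-adjusted logistic regression recovers the configured exposure odds
#' ratios.
#'
#' @param n number of eyes.
#' @param seed RNG seed.
#' @param assoc association preset.
#' @return data.frame with `age`, `impaired` and lab columns.
#' @export
simulate_systemic_cohort <- function(n, seed = 1L, assoc = default_assoc_preset()) {
  base <- with_seed(seed, {
    age <- rnorm_trunc(n, 49.6, 8.1, 25, 75)
    eta <- assoc$impaired_base_logit + assoc$impaired_age_coef * (age - 50)
    data.frame(age = age, impaired = rbinom(n, 1L, plogis(eta)))
  })
  out <- sample_systemic(base, base$impaired, assoc, seed = seed + 1L)
  out
}
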