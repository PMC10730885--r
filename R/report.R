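#' Build the full statistical report for a measured cohort
#'
#' Assembles the study's analysis set on a cohort with measured image
#' metrics: group characteristics, three-group flow and outer-retina
#' comparisons, pairwise correlations, ROC cutoffs for discriminating
#' diabetic from control eyes, the two-threshold impaired-flow odds ratio,
#' and the age-adjusted one-exposure-at-a-time logistic table.  The report
#' is a deterministic function of its input.
#'
#' @param cohort data.frame with measured columns (`ccfa_ratio`,
#'   `cv_ccfa`, `vld`) joined to the tabular record, e.g. the output of
#'   [run_cohort_images()].
#' @param cutoffs CCFA / CV cutoffs for the impaired-flow rule; `NULL`
#'   (default) derives both from the cohort's own ROC Youden indices.
#' @return a `stats_report` list with sections `characteristics`,
#'   `group_flow`, `correlations`, `roc`, `classification`, `logistic`.
#' @export
build_report <- function(cohort, cutoffs = NULL) {
  required <- c("eye_id", "group", "age", "ccfa_ratio", "cv_ccfa", "vld",
                "pros_length", "rpe_volume")
  miss <- setdiff(required, names(cohort))
  if (length(miss))
    stop("schema error: missing columns: ", paste(miss, collapse = ", "))
  grp_sizes <- table(factor(cohort$group,
                            levels = c("control", "dm_no_dr", "dr")))

  characteristics <- lapply(
    intersect(c("age", "bcva_logmar", "central_retinal_thickness"),
              names(cohort)),
    function(v) group_compare(cohort, v))
  names(characteristics) <- vapply(characteristics, `[[`, "", "variable")

  flow_vars <- c("ccfa_ratio", "cv_ccfa", "vld", "pros_length", "rpe_volume")
  group_flow <- lapply(flow_vars, function(v) group_compare(cohort, v))
  names(group_flow) <- flow_vars

  pairs <- list(c("ccfa_ratio", "vld"), c("cv_ccfa", "vld"),
                c("ccfa_ratio", "pros_length"), c("ccfa_ratio", "rpe_volume"),
                c("vld", "pros_length"), c("vld", "rpe_volume"))
  correlations <- lapply(pairs, function(pp) {
    ok <- complete.cases(cohort[, pp])
    r <- if (sum(ok) >= 3) pearson_r(cohort[[pp[1]]][ok], cohort[[pp[2]]][ok])
         else list(r = NA_real_, p = NA_real_, reason = "too_few_observations")
    c(list(x = pp[1], y = pp[2]), r)
  })

  diabetic <- cohort$group %in% c("dm_no_dr", "dr")
  ok_roc <- is.finite(cohort$ccfa_ratio) & is.finite(cohort$cv_ccfa)
  roc <- if (any(diabetic[ok_roc]) && any(!diabetic[ok_roc])) {
    list(ccfa = roc_auc(cohort$ccfa_ratio[ok_roc], diabetic[ok_roc], "low"),
         cv = roc_auc(cohort$cv_ccfa[ok_roc], diabetic[ok_roc], "high"))
  } else list(skipped = "need both diabetic and control eyes")

  if (is.null(cutoffs) && !is.null(roc$ccfa))
    cutoffs <- c(roc$ccfa$youden_cutoff, roc$cv$youden_cutoff)
  if (is.null(cutoffs)) cutoffs <- c(65.9, 0.140)
  impaired <- classify_impaired(cohort$ccfa_ratio, cohort$cv_ccfa, cutoffs)
  classification <- if (!is.null(roc$ccfa)) {
    a <- sum(impaired & diabetic, na.rm = TRUE)
    b <- sum(impaired & !diabetic, na.rm = TRUE)
    cc <- sum(!impaired & diabetic, na.rm = TRUE)
    d <- sum(!impaired & !diabetic, na.rm = TRUE)
    c(list(cutoffs = cutoffs), unclass(odds_ratio_2x2(a, b, cc, d)))
  } else list(skipped = "roc unavailable")

  exposures <- intersect(
    c("hba1c_ge_7", "sbp_ge_135", "dbp_ge_85", "hdl_lt_40", "ldl_ge_140",
      "ldl_hdl_ge_2.5", "tg_ge_150", "tc_ge_220", "nonhdl_ge_170"),
    names(cohort))
  logistic <- if (length(exposures) && sum(impaired, na.rm = TRUE) > 1 &&
                  sum(!impaired, na.rm = TRUE) > 1) {
    dat <- cohort[is.finite(cohort$ccfa_ratio), ]
    dat$impaired_measured <- classify_impaired(dat$ccfa_ratio, dat$cv_ccfa,
                                               cutoffs)
    fit_exposure_table(dat, "impaired_measured", exposures)
  } else list(skipped = "impaired-flow outcome is degenerate")

  structure(list(
    n_per_group = as.list(grp_sizes),
    characteristics = characteristics,
    group_flow = group_flow,
    correlations = correlations,
    roc = roc,
    classification = classification,
    logistic = logistic
  ), class = "stats_report")
}

#' Write a stats report to disk
#'
#' `report.json` plus per-section CSV tables under `tables/`.
#'
#' @param report a `stats_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(file.path(dir, "tables"), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass_deep(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  gf <- do.call(rbind, lapply(report$group_flow, function(gc) {
    if (gc$skipped) return(NULL)
    do.call(rbind, lapply(names(gc$groups), function(g) {
      s <- gc$groups[[g]]
      data.frame(variable = gc$variable, group = g, n = s$n, mean = s$mean,
                 sd = s$sd, kruskal_p = gc$kruskal_p)
    }))
  }))
  write.csv(gf, file.path(dir, "tables", "group_flow.csv"), row.names = FALSE)
  if (is.data.frame(report$logistic))
    write.csv(report$logistic, file.path(dir, "tables", "logistic.csv"),
              row.names = FALSE)
  invisible(dir)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Run the whole synthetic study end to end
#'
#' Cohort generation, preset calibration, image rendering and measurement,
#' and the statistical report; the one-call entry point mirroring the
#' package's command-line interface.
#'
#' @param config list; honours `n_per_group`, `base_seed`, `presets`
#'   (calibrated or not), `calibration_seed`, `side_px`, `noise`.
#' @param out optional output directory; when given, writes `cohort.csv`,
#'   `metrics.csv`, `report.json` and tables.
#' @return list with `cohort` (measured) and `report`.
#' @export
run_all <- function(config = list(), out = NULL) {
  presets <- config$presets %||% default_presets()
  if (any(vapply(presets, function(p) is.na(p$void_param), TRUE)))
    presets <- calibrate_presets(presets,
                                 seed = config$calibration_seed %||% 1L)
  cohort <- generate_cohort(config)
  qf <- quality_filter(cohort)
  measured <- run_cohort_images(qf$included, presets,
                                side_px = config$side_px %||% 512L,
                                noise = config$noise %||% TRUE)
  report <- build_report(measured)
  if (!is.null(out)) {
    write_cohort_csv(cohort, file.path(out, "cohort.csv"))
    write_cohort_csv(measured, file.path(out, "metrics.csv"))
    if (nrow(qf$exclusions))
      write_cohort_csv(qf$exclusions, file.path(out, "exclusions.csv"))
    write_report(report, out)
  }
  list(cohort = measured, report = report, presets = presets)
}
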