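#' Calibrate a group preset against the measurement pipeline
#'
#' Self-calibration of the simulator so that *measured* statistics hit the
#' preset targets: monotone bisection on `void_param` until the mean
#' measured CCFA ratio over `n_eyes` simulated anchor eyes is within `tol`
#' of `target_ccfa_mean`, then bisection on `heterogeneity_param` until the
#' mean measured tile CV is within `cv_tol` of `target_cv_mean`.  Because
#' void clustering feeds back weakly on the binarization bias (and hence on
#' the measured mean CCFA), the two stages are repeated for `cycles`
#' rounds, each void bisection running at the current heterogeneity.  The
#' same eye seeds are reused at every bisection step (common random
#' numbers), so each stage bisects a smooth monotone function; bisection
#' continues until the achieved value is within tolerance *and* the
#' bracket is narrow, so the returned parameters do not inherit a
#' tolerance-sized offset.
#'
#' The CV stage first measures the heterogeneity floor (tile CV at zero
#' heterogeneity, set by void granularity and binarization noise); a CV
#' target below that floor is not reachable and raises a calibration
#' error, as does any bracket that fails to straddle its target.
#'
#' @param preset a `GroupPreset`.
#' @param pipeline function `(preset, seed) -> list(ccfa, cv)`; defaults to
#'   [measure_cc_eye()] at the device-assumed axial length.
#' @param tol CCFA tolerance in percentage points (default 0.5).
#' @param cv_tol CV tolerance (default 0.01).
#' @param max_iter bisection iteration cap per stage.
#' @param seed base seed; anchor eyes use `seed + 1 .. seed + n_eyes`.
#' @param n_eyes anchor eyes per bisection step (>= 20).
#' @param h_max upper bracket for the heterogeneity log-amplitude.
#' @param calibrate_cv also run the CV stage (default TRUE).
#' @param cycles void/CV alternation rounds (default 2).
#' @param ... passed to the default pipeline ([measure_cc_eye()]).
#' @return the preset with `void_param`, `heterogeneity_param`, `cv_floor`,
#'   `achieved_ccfa`, `achieved_cv` filled in.
#' @export
calibrate_preset <- function(preset, pipeline = NULL, tol = 0.5,
                             cv_tol = 0.01, max_iter = 25L, seed = 1L,
                             n_eyes = 20L, h_max = 1.5,
                             calibrate_cv = TRUE, cycles = 2L, ...) {
  validate_preset(preset)
  stopifnot(tol > 0, cv_tol > 0, n_eyes >= 2)
  if (is.null(pipeline))
    pipeline <- function(p, s) measure_cc_eye(p, s, ...)
  seeds <- seed + seq_len(n_eyes)
  measure <- function(v, h) {
    p <- preset; p$void_param <- v; p$heterogeneity_param <- h
    res <- lapply(seeds, function(s) pipeline(p, s))
    c(ccfa = mean(vapply(res, `[[`, 1, "ccfa")),
      cv = mean(vapply(res, `[[`, 1, "cv")))
  }
  bisect <- function(f, target, lo, hi, tol, decreasing, min_bracket, what) {
    # f must be monotone; returns list(x, value) with |value - target| <= tol
    best <- NULL
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (is.null(best) || abs(fm$value - target) < abs(best$value - target))
        best <- list(x = mid, value = fm$value, all = fm$all)
      if (abs(fm$value - target) <= tol && (hi - lo) / 2 <= min_bracket)
        return(best)
      go_up <- if (decreasing) fm$value > target else fm$value < target
      if (go_up) lo <- mid else hi <- mid
    }
    if (abs(best$value - target) <= tol) return(best)
    stop(sprintf("convergence error: %s residual %.4f after %d iterations",
                 what, best$value - target, max_iter))
  }

  h_cur <- if (is.na(preset$heterogeneity_param)) 0 else preset$heterogeneity_param
  v_cur <- NA_real_
  achieved <- NULL
  for (cyc in seq_len(max(1L, cycles))) {
    # --- void_param stage: measured CCFA is decreasing in v ---
    target <- preset$target_ccfa_mean
    f_lo <- measure(0, h_cur)
    if (abs(f_lo[["ccfa"]] - target) <= tol && target >= f_lo[["ccfa"]]) {
      v_cur <- 0; achieved <- f_lo
    } else if (f_lo[["ccfa"]] < target - tol) {
      stop(sprintf(paste0("calibration error: bracket does not straddle target ",
                          "(CCFA at void_param 0 is %.2f, below target %.2f)"),
                   f_lo[["ccfa"]], target))
    } else {
      f_hi <- measure(1, h_cur)
      if (f_hi[["ccfa"]] > target + tol)
        stop(sprintf(paste0("calibration error: bracket does not straddle target ",
                            "(CCFA at void_param 1 is %.2f, above target %.2f)"),
                     f_hi[["ccfa"]], target))
      r <- bisect(function(v) { m <- measure(v, h_cur)
                                list(value = m[["ccfa"]], all = m) },
                  target, 0, 1, tol, decreasing = TRUE,
                  min_bracket = 1 / 256, what = "CCFA")
      v_cur <- r$x; achieved <- r$all
    }
    if (!calibrate_cv) break

    # --- heterogeneity stage: measured tile CV is increasing in h ---
    cv_target <- preset$target_cv_mean
    g_lo <- measure(v_cur, 0)
    preset$cv_floor <- g_lo[["cv"]]
    if (abs(g_lo[["cv"]] - cv_target) <= cv_tol && cv_target <= g_lo[["cv"]]) {
      h_cur <- 0; achieved <- g_lo
    } else if (g_lo[["cv"]] > cv_target + cv_tol) {
      stop(sprintf(paste0("calibration error: CV target %.3f is below the ",
                          "heterogeneity floor %.3f for this tile size"),
                   cv_target, g_lo[["cv"]]))
    } else {
      g_hi <- measure(v_cur, h_max)
      if (g_hi[["cv"]] < cv_target - cv_tol)
        stop(sprintf(paste0("calibration error: bracket does not straddle target ",
                            "(CV at h_max %.2f is %.3f, below target %.3f)"),
                     h_max, g_hi[["cv"]], cv_target))
      r <- bisect(function(h) { m <- measure(v_cur, h)
                                list(value = m[["cv"]], all = m) },
                  cv_target, 0, h_max, cv_tol, decreasing = FALSE,
                  min_bracket = h_max / 256, what = "CV")
      h_cur <- r$x; achieved <- r$all
    }
  }
  preset$void_param <- v_cur
  preset$heterogeneity_param <- h_cur
  preset$achieved_ccfa <- achieved[["ccfa"]]
  preset$achieved_cv <- achieved[["cv"]]
  preset
}

#' Calibrate all group presets
#'
#' Convenience wrapper running [calibrate_preset()] for each group.
#'
#' @param presets named list of presets (default [default_presets()]).
#' @param seed base calibration seed.
#' @param ... passed to [calibrate_preset()].
#' @return named list of calibrated presets.
#' @export
calibrate_presets <- function(presets = default_presets(), seed = 1L, ...) {
  out <- presets
  for (g in names(presets))
    out[[g]] <- calibrate_preset(presets[[g]], seed = seed, ...)
  out
}
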