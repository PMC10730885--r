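# Mann-Whitney U test wrapper: exact enumeration when both groups have
# n <= 8 and there are no ties, otherwise the normal approximation with
# tie and continuity correction.
mw_test <- function(x, y, correct = TRUE) {
  exact <- length(x) <= 8 && length(y) <= 8 &&
    !any(duplicated(c(x, y)))
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = correct,
                alternative = "two.sided"))
  list(U = unname(ht$statistic), p = ht$p.value, exact = exact)
}

#' Three-group nonparametric comparison of one variable
#'
#' Kruskal-Wallis H (with tie correction) across all groups plus pairwise
#' two-sided Mann-Whitney U tests (exact enumeration when both groups have
#' at most 8 observations and no ties; normal approximation with tie and
#' continuity correction otherwise).  Groups with fewer than 2 finite
#' values are flagged and the comparison is skipped.
#'
#' @param data data.frame.
#' @param variable name of the numeric column to compare.
#' @param group_col name of the grouping column (default `"group"`).
#' @return a `group_comparison` list: per-group summaries, `kruskal_H`,
#'   `kruskal_p`, and a `pairwise` data.frame of U and p per group pair.
#' @export
group_compare <- function(data, variable, group_col = "group") {
  stopifnot(variable %in% names(data), group_col %in% names(data))
  v <- data[[variable]]
  g <- as.character(data[[group_col]])
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  sp <- split(v, g)
  summaries <- lapply(sp, function(x) {
    list(n = length(x), mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_,
         range = range(x))
  })
  degenerate <- names(sp)[vapply(sp, length, 1L) < 2]
  if (length(sp) - length(degenerate) < 2) {
    return(structure(list(variable = variable, groups = summaries,
                          kruskal_H = NA_real_, kruskal_p = NA_real_,
                          pairwise = NULL, skipped = TRUE,
                          degenerate_groups = degenerate),
                     class = "group_comparison"))
  }
  ok <- !(g %in% degenerate)
  kw <- kruskal.test(v[ok], factor(g[ok]))
  prs <- utils::combn(sort(setdiff(names(sp), degenerate)), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
    a <- prs[1, i]; b <- prs[2, i]
    mt <- mw_test(sp[[a]], sp[[b]])
    data.frame(group1 = a, group2 = b, U = mt$U, p = mt$p, exact = mt$exact,
               stringsAsFactors = FALSE)
  }))
  structure(list(variable = variable, groups = summaries,
                 kruskal_H = unname(kw$statistic), kruskal_p = kw$p.value,
                 pairwise = pairwise, skipped = FALSE,
                 degenerate_groups = degenerate),
            class = "group_comparison")
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors, `n >= 3`, finite.
#' @return list with `r` and `p` (t-transform with n-2 df), or `r = NA`
#'   with `reason = "zero_variance"` when either input is constant.
#' @export
pearson_r <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 finite paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, reason = "zero_variance"))
  ht <- cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' ROC curve summary with Youden cutoff
#'
#' AUC is computed through the Mann-Whitney U identity with ties counted
#' one half.  The Youden cutoff maximizes sensitivity + specificity - 1
#' over the observed values; among ties the cutoff closest to the pooled
#' median (the least extreme threshold) is chosen.  `direction = "low"`
#' flags disease when the value is strictly below the cutoff (as for the
#' CCFA ratio); `direction = "high"` flags disease when the value is at or
#' above the cutoff (as for the CV of the CCFA ratio).
#'
#' @param values numeric marker values.
#' @param labels logical or 0/1; `TRUE`/1 = disease.
#' @param direction which tail flags disease.
#' @return a `roc_result`: `auc`, `youden_cutoff`, `sensitivity`,
#'   `specificity`, `direction`, `n_disease`, `n_control`.
#' @export
roc_auc <- function(values, labels, direction = c("low", "high")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  score <- if (direction == "low") -values else values
  r <- rank(score)                      # midranks: ties count 1/2
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cand <- sort(unique(values))
  cand <- c(cand, cand[length(cand)] + 1)    # include the all/none extremes
  stat <- vapply(cand, function(cc) {
    flag <- if (direction == "low") values < cc else values >= cc
    sens <- sum(flag & labels) / n1
    spec <- sum(!flag & !labels) / n0
    c(sens + spec - 1, sens, spec)
  }, numeric(3))
  jmax <- max(stat[1, ])
  tied <- which(stat[1, ] >= jmax - 1e-12)
  best <- tied[which.min(abs(cand[tied] - stats::median(values)))]
  structure(list(auc = auc, youden_cutoff = cand[best],
                 sensitivity = stat[2, best], specificity = stat[3, best],
                 direction = direction, n_disease = n1, n_control = n0),
            class = "roc_result")
}

#' Odds ratio of a 2x2 table
#'
#' Cells follow the exposed/unexposed by case/control layout:
#' `a` exposed cases, `b` exposed controls, `c` unexposed cases,
#' `d` unexposed controls; OR = ad / bc.  A zero cell triggers the
#' Haldane-Anscombe correction (+0.5 to every cell, flagged).  The
#' confidence interval uses the Woolf log-SE method; the p value is the
#' Pearson chi-square, or Fisher's exact test when any expected cell is
#' below 5.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @param conf_level confidence level (default 0.95).
#' @return an `odds_ratio_result` list.
#' @export
odds_ratio_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be nonnegative integers")
  if (sum(cells) == 0) stop("empty table")
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc[1] * cc[4]) / (cc[2] * cc[3])
  se <- sqrt(sum(1 / cc))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tab <- matrix(cells, 2, 2, byrow = TRUE)   # rows: case/control by exposure
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  p <- if (any(expected < 5)) fisher.test(tab)$p.value
       else suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  structure(list(a = a, b = b, c = c, d = d, or = or,
                 ci_low = exp(log(or) - zq * se),
                 ci_high = exp(log(or) + zq * se),
                 p = p, haldane_corrected = corrected),
            class = "odds_ratio_result")
}

#' Logistic regression with Wald inference and separation handling
#'
#' Maximum-likelihood fit (iteratively reweighted least squares via
#' `glm`), reporting per-covariate coefficient, odds ratio, Wald 95% CI
#' and p value.  Complete or quasi-separation (non-convergence or any
#' |coefficient| > 15) sets the `separation` flag and suppresses the CI.
#'
#' @param outcome binary vector (0/1 or logical).
#' @param covariates data.frame of numeric covariates.
#' @return a `logistic_result`: data.frame `coefficients` plus
#'   `converged` and `separation` flags.
#' @export
fit_logistic <- function(outcome, covariates) {
  y <- as.integer(as.logical(outcome))
  stopifnot(length(y) == nrow(covariates))
  if (length(unique(y)) < 2) {
    # one-class outcome: association unidentifiable
    tab <- data.frame(term = c("(Intercept)", colnames(covariates)),
                      coef = NA_real_, or = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
    return(structure(list(coefficients = tab, converged = FALSE,
                          separation = TRUE),
                     class = "logistic_result"))
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  df <- data.frame(.y = y, covariates, check.names = FALSE)
  fit <- suppressWarnings(
    glm(.y ~ ., data = df, family = binomial(),
        control = list(maxit = 100, epsilon = 1e-10)))
  cf <- coef(fit)
  separation <- !fit$converged || any(abs(cf[-1]) > 15)
  se <- sqrt(diag(vcov(fit)))
  z <- cf / se
  tab <- data.frame(
    term = names(cf), coef = unname(cf), or = exp(unname(cf)),
    ci_low = if (separation) NA_real_ else exp(unname(cf) - 1.96 * se),
    ci_high = if (separation) NA_real_ else exp(unname(cf) + 1.96 * se),
    p = 2 * pnorm(-abs(unname(z))),
    stringsAsFactors = FALSE
  )
  structure(list(coefficients = tab, converged = fit$converged,
                 separation = separation),
            class = "logistic_result")
}

#' Age-adjusted one-exposure-at-a-time logistic models
#'
#' Fits `outcome ~ exposure + age` separately for each exposure, mirroring
#' a risk-factor table built from single-exposure age-adjusted models.
#'
#' @param data data.frame containing `outcome_col`, `age` and the exposures.
#' @param outcome_col name of the binary outcome column.
#' @param exposures character vector of exposure column names.
#' @return data.frame with one row per exposure (OR, Wald CI, p,
#'   separation flag).
#' @export
fit_exposure_table <- function(data, outcome_col, exposures) {
  do.call(rbind, lapply(exposures, function(ex) {
    fit <- fit_logistic(data[[outcome_col]],
                        data[, c(ex, "age"), drop = FALSE])
    row <- fit$coefficients[fit$coefficients$term == ex, ]
    data.frame(exposure = ex, or = row$or, ci_low = row$ci_low,
               ci_high = row$ci_high, p = row$p,
               separation = fit$separation, stringsAsFactors = FALSE)
  }))
}
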