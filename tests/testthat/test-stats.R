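test_that("group comparison matches exact small-sample enumeration", {
  d <- data.frame(v = c(1, 2, 3, 4), g = c("a", "a", "b", "b"))
  gc <- group_compare(d, "v", "g")
  pw <- gc$pairwise
  expect_equal(pw$U, 0)
  expect_equal(pw$p, 1 / 3, tolerance = 1e-9)   # 2 of 6 orderings as extreme
  expect_true(pw$exact)

  # identical groups: H ~ 0, p ~ 1 (with ties correction H is exactly 0 here)
  d2 <- data.frame(v = rep(c(5, 6, 7), 3), g = rep(c("a", "b", "c"), each = 3))
  gc2 <- group_compare(d2, "v", "g")
  expect_lt(gc2$kruskal_H, 1e-9)
  expect_gt(gc2$kruskal_p, 0.99)

  # order invariance
  set.seed(5)
  d3 <- data.frame(v = rnorm(30), g = rep(c("a", "b", "c"), 10))
  perm <- sample(30)
  gc3a <- group_compare(d3, "v", "g")
  gc3b <- group_compare(d3[perm, ], "v", "g")
  expect_equal(gc3a$kruskal_p, gc3b$kruskal_p)
  expect_equal(gc3a$pairwise$p, gc3b$pairwise$p)

  # degenerate group flagged and skipped
  d4 <- data.frame(v = c(1, 2, 3, 4, 5), g = c("a", "a", "b", "b", "c"))
  gc4 <- group_compare(d4, "v", "g")
  expect_equal(gc4$degenerate_groups, "c")
  expect_false(gc4$skipped)
})

test_that("pearson_r matches hand computation and handles degeneracy", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1.0)
  r <- pearson_r(c(1, 2, 3), c(2, 4, 5))
  expect_equal(r$r, 3 / sqrt(2 * 4.66666666667), tolerance = 1e-8)
  expect_equal(round(r$r, 5), 0.98198)
  z <- pearson_r(rep(1, 5), 1:5)
  expect_true(is.na(z$r))
  expect_equal(z$reason, "zero_variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("roc_auc reproduces worked examples and the U identity", {
  expect_equal(roc_auc(c(1, 2, 3, 4, 5, 6),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), "low")$auc, 1)
  expect_equal(roc_auc(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE), "low")$auc,
               0.75)
  # label flip symmetry and brute-force pair counting on random data
  set.seed(17)
  for (rep in 1:10) {
    v <- sample(1:20, 24, replace = TRUE)   # ties present
    lab <- rep(c(TRUE, FALSE), 12)
    a <- roc_auc(v, lab, "low")$auc
    expect_equal(a, auc_brute(v, lab, "low"), tolerance = 1e-12)
    expect_equal(roc_auc(v, !lab, "low")$auc, 1 - a, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("roc_auc agrees with pROC and its Youden cutoff separates as declared", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (rep in 1:5) {
    v <- c(rnorm(30, 60, 6), rnorm(30, 67, 5))
    lab <- rep(c(TRUE, FALSE), each = 30)
    ours <- roc_auc(v, lab, "low")
    ref <- pROC::roc(response = lab, predictor = v, direction = ">",
                     quiet = TRUE)
    expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
    # the reported sens/spec are attained at the reported cutoff
    flag <- v < ours$youden_cutoff
    expect_equal(mean(flag[lab]), ours$sensitivity)
    expect_equal(mean(!flag[!lab]), ours$specificity)
  }
})

test_that("odds ratio table arithmetic, symmetry and zero-cell policy", {
  or <- odds_ratio_2x2(24, 9, 2, 10)
  expect_equal(or$or, 240 / 18, tolerance = 1e-12)
  expect_lt(or$p, 0.01)
  expect_true(or$ci_low > 1)
  expect_equal(odds_ratio_2x2(1, 1, 1, 1)$or, 1)

  z <- odds_ratio_2x2(5, 0, 2, 10)
  expect_true(z$haldane_corrected)
  expect_equal(z$or, (5.5 * 10.5) / (0.5 * 2.5), tolerance = 1e-12)

  # swapping both rows and columns preserves the OR; rows only inverts it
  set.seed(29)
  for (rep in 1:5) {
    cells <- sample(1:30, 4)
    o1 <- odds_ratio_2x2(cells[1], cells[2], cells[3], cells[4])$or
    o2 <- odds_ratio_2x2(cells[4], cells[3], cells[2], cells[1])$or
    o3 <- odds_ratio_2x2(cells[3], cells[4], cells[1], cells[2])$or
    expect_equal(o1, o2, tolerance = 1e-12)
    expect_equal(o3, 1 / o1, tolerance = 1e-12)
  }
  expect_error(odds_ratio_2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("logistic regression recovers known effects and flags separation", {
  set.seed(31)
  n <- 5000
  age <- rnorm(n, 50, 8)
  x <- rbinom(n, 1, 0.4)
  # null: OR near 1
  y0 <- rbinom(n, 1, plogis(-0.2 + 0.01 * (age - 50)))
  f0 <- fit_logistic(y0, data.frame(x = x, age = age))
  expect_true(f0$coefficients$or[2] > 0.85 && f0$coefficients$or[2] < 1.18)
  # effect recovery: OR = 5 within 15%
  y1 <- rbinom(n, 1, plogis(-1 + log(5) * x + 0.02 * (age - 50)))
  f1 <- fit_logistic(y1, data.frame(x = x, age = age))
  expect_lt(abs(f1$coefficients$or[2] - 5) / 5, 0.15)
  expect_true(f1$converged)
  # perfect prediction: separation flag, no CI
  ys <- x
  fs <- fit_logistic(ys, data.frame(x = x, age = age))
  expect_true(fs$separation)
  expect_true(is.na(fs$coefficients$ci_low[2]))
  # rank deficiency is an error
  expect_error(fit_logistic(y1, data.frame(x = x, x2 = 2 * x)), "rank")
})

test_that("report has all sections, is deterministic, and degrades gracefully", {
  set.seed(37)
  coh <- generate_cohort(list(base_seed = 3))
  # attach plausible measured columns without the image pipeline
  coh$ccfa_ratio <- coh$ccfa_target + rnorm(45, 0, 0.5)
  coh$cv_ccfa <- coh$cv_target
  coh$vld <- coh$vld_target
  rep1 <- build_report(coh)
  rep2 <- build_report(coh)
  expect_identical(rep1, rep2)
  expect_named(rep1, c("n_per_group", "characteristics", "group_flow",
                       "correlations", "roc", "classification", "logistic"))
  expect_s3_class(rep1$roc$ccfa, "roc_result")
  expect_true(is.finite(rep1$classification$or))
  # serializes to valid JSON
  tmp <- tempfile()
  write_report(rep1, tmp)
  j <- jsonlite::read_json(file.path(tmp, "report.json"))
  expect_true(all(c("group_flow", "roc", "logistic") %in% names(j)))
  unlink(tmp, recursive = TRUE)

  # missing column -> schema error naming it
  expect_error(build_report(coh[, setdiff(names(coh), "vld")]), "vld")

  # one group absent -> comparisons skipped, report still emitted
  sub <- coh[coh$group != "control", ]
  rep3 <- build_report(sub)
  expect_true(is.list(rep3$roc))
  expect_true(!is.null(rep3$roc$skipped) || !is.null(rep3$classification$skipped))
})
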