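test_that("cohort has the configured sizes and is byte-identical per seed", {
  coh <- generate_cohort(list(n_per_group = c(12, 15, 18), base_seed = 1))
  expect_equal(nrow(coh), 45)
  expect_equal(as.numeric(table(factor(coh$group,
    levels = c("control", "dm_no_dr", "dr")))), c(12, 15, 18))
  coh2 <- generate_cohort(list(n_per_group = c(12, 15, 18), base_seed = 1))
  expect_identical(coh, coh2)
  coh3 <- generate_cohort(list(base_seed = 2))
  expect_false(identical(coh$ccfa_target, coh3$ccfa_target))
})

test_that("no emitted eye violates the inclusion invariants", {
  coh <- do.call(rbind, lapply(1:4, function(s)
    generate_cohort(list(base_seed = s))))
  expect_true(all(coh$bcva_logmar < 0.05))
  expect_true(all(coh$axial_length < 27))
  labs <- c("hba1c", "systolic_bp", "diastolic_bp", "hdl_c", "ldl_c",
            "triglyceride", "total_cholesterol", "non_hdl_c")
  for (v in labs) expect_true(all(coh[[v]] > 0), label = v)
  expect_true(all(coh$ccfa_target > 0 & coh$ccfa_target < 100))
  expect_true(all(coh$quality_index > 7))
})

test_that("zero-variance presets yield exactly the preset means", {
  pr <- default_presets()
  for (g in names(pr)) {
    pr[[g]]$pros_sd <- 0
    pr[[g]]$target_ccfa_sd <- 0
  }
  coh <- generate_cohort(list(n_per_group = c(2, 2, 2), base_seed = 5,
                              presets = pr))
  expect_equal(coh$pros_length[coh$group == "control"], rep(64.5, 2))
  expect_equal(coh$pros_length[coh$group == "dr"], rep(56.7, 2))
  expect_equal(coh$ccfa_target[coh$group == "dm_no_dr"], rep(62.7, 2))
})

test_that("group means converge to preset targets (law of large numbers)", {
  coh <- generate_cohort(list(n_per_group = c(500, 500, 500), base_seed = 7),
                         fill_systemic = FALSE)
  ctrl <- coh[coh$group == "control", ]
  expect_lt(abs(mean(ctrl$pros_length) - 64.5), 0.5)
  # 3 sigma / sqrt(n) bounds per channel
  checks <- list(c("ccfa_target", 69.1, 3.8), c("vld_target", 21.2, 0.7),
                 c("cv_target", 0.124, 0.019))
  for (ch in checks) {
    m <- mean(ctrl[[ch[1]]])
    expect_lt(abs(m - as.numeric(ch[2])), 3 * as.numeric(ch[3]) / sqrt(500),
              label = ch[1])
  }
  dr <- coh[coh$group == "dr", ]
  expect_lt(abs(mean(dr$ccfa_target) - 58.4), 3 * 6.1 / sqrt(500))
})

test_that("latent severity wiring reproduces the configured target correlation", {
  # pooled correlation between CCFA and VLD targets at equal group weights
  coh <- generate_cohort(list(n_per_group = c(1700, 1700, 1700),
                              base_seed = 11), fill_systemic = FALSE)
  r <- cor(coh$ccfa_target, coh$vld_target)
  expect_lt(abs(r - 0.572), 0.03)
  # signs of the published cross-channel correlations
  expect_gt(cor(coh$ccfa_target, coh$pros_length), 0)
  expect_lt(cor(coh$ccfa_target, coh$rpe_volume), 0)
  expect_lt(cor(coh$cv_target, coh$vld_target), 0)
})

test_that("invalid presets raise configuration errors naming the field", {
  pr <- default_presets()
  pr$control$target_ccfa_sd <- -1
  expect_error(generate_cohort(list(presets = pr)), "target_ccfa_sd")
  pr <- default_presets()
  pr$dr$target_ccfa_mean <- 130
  expect_error(generate_cohort(list(presets = pr)), "target_ccfa_mean")
})

test_that("systemic sampling recovers the configured association", {
  # null association: identical exceedance rates
  assoc <- default_assoc_preset()
  assoc$exposures$hba1c_ge_7$or <- 1
  assoc$exposures$hba1c_ge_7$age_coef <- 0
  base <- data.frame(age = rep(50, 4000),
                     eye_id = sprintf("e%04d", 1:4000))
  imp <- rep(c(TRUE, FALSE), 2000)
  lab <- sample_systemic(base, imp, assoc, seed = 3)
  p1 <- mean(lab$hba1c_ge_7[imp]); p0 <- mean(lab$hba1c_ge_7[!imp])
  expect_lt(abs(p1 - p0), 0.04)

  # default preset: crude 2x2 OR within 15% of 4.992 at n = 5000
  d <- simulate_systemic_cohort(5000, seed = 13)
  a <- sum(d$hba1c_ge_7 == 1 & d$impaired == 1)
  b <- sum(d$hba1c_ge_7 == 1 & d$impaired == 0)
  cc <- sum(d$hba1c_ge_7 == 0 & d$impaired == 1)
  dd <- sum(d$hba1c_ge_7 == 0 & d$impaired == 0)
  crude <- (a * dd) / (b * cc)
  expect_lt(abs(crude - 4.992) / 4.992, 0.15)
  # continuous values are consistent with their indicator
  expect_true(all(d$hba1c[d$hba1c_ge_7 == 1] >= 7))
  expect_true(all(d$hba1c[d$hba1c_ge_7 == 0] < 7))
  expect_true(all(d$hdl_c[d$hdl_lt_40 == 1] < 40))

  # degenerate design: all eyes impaired -> separation reported downstream
  allimp <- sample_systemic(base, rep(TRUE, 4000), default_assoc_preset(),
                            seed = 5)
  allimp$imp <- TRUE
  f <- fit_logistic(allimp$imp, allimp[, c("hba1c_ge_7", "age")])
  expect_true(f$separation)
  expect_false(f$converged)
})
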