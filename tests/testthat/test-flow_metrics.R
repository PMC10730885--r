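test_that("Phansalkar threshold matches the closed form on constant images", {
  # m = 0.5, s = 0: T = 0.5 * (1 + 2 exp(-5) - 0.25)
  thr <- phansalkar_threshold(matrix(0.5, 24, 24))
  expect_equal(unique(as.numeric(thr)), 0.5 * (1 + 2 * exp(-5) - 0.25),
               tolerance = 1e-12)
  # m = 0 annihilates the product
  expect_true(all(phansalkar_threshold(matrix(0, 24, 24)) == 0))
})

test_that("Phansalkar map equals the brute-force sliding-window oracle", {
  params <- phansalkar_params(window_radius = 2)
  set.seed(11)
  for (rep in 1:4) {
    img <- matrix(runif(24 * 24), 24, 24)
    expect_equal(phansalkar_threshold(img, params),
                 phansalkar_brute(img, params), tolerance = 1e-10)
  }
  # checkerboard: centre pixel against a hand-computable window
  img <- matrix(rep(c(0, 1), length.out = 81), 9, 9)
  p1 <- phansalkar_params(window_radius = 1)
  expect_equal(phansalkar_threshold(img, p1)[5, 5],
               phansalkar_brute(img, p1)[5, 5], tolerance = 1e-12)
})

test_that("binarization polarity and normalization checks", {
  expect_true(all(binarize_flow(matrix(0.5, 24, 24))$mask))   # 0.5 > 0.3817
  expect_false(any(binarize_flow(matrix(0, 24, 24))$mask))    # strict >
  expect_error(phansalkar_threshold(matrix(1.5, 24, 24)), "normalize")
})

test_that("ccfa_ratio counts flow pixels and is monotone in added flow", {
  m <- matrix(FALSE, 4, 4); m[1:6] <- TRUE
  expect_equal(ccfa_ratio(m), 37.5)
  expect_equal(ccfa_ratio(matrix(TRUE, 3, 3)), 100)
  set.seed(21)
  base <- matrix(runif(36 * 36) < 0.4, 36, 36)
  grown <- base; grown[sample(which(!grown), 50)] <- TRUE
  expect_gt(ccfa_ratio(grown), ccfa_ratio(base))
})

test_that("tile CV reproduces the worked example and its invariants", {
  # 2x2 grid with tile ratios 1, .5, .5, 0: mean .5, sample sd sqrt(1/6)
  m <- matrix(FALSE, 4, 4)
  m[1:2, 1:2] <- TRUE                         # tile (1,1) = 1.0
  m[1:2, 3] <- TRUE                           # tile (1,2) = 0.5
  m[3, 1:2] <- TRUE                           # tile (2,1) = 0.5
  res <- cv_of_ccfa(m, grid = 2)
  expect_equal(sort(res$tile_ratios), c(0, 0.5, 0.5, 1))
  expect_equal(res$cv, sqrt(1 / 6) / 0.5, tolerance = 1e-12)

  # homogeneous mask: cv = 0
  expect_equal(cv_of_ccfa(matrix(TRUE, 36, 36))$cv, 0)

  # all-false: explicit not-a-value
  res0 <- cv_of_ccfa(matrix(FALSE, 36, 36))
  expect_true(is.na(res0$cv))
  expect_equal(res0$reason, "zero_mean_flow")
})

test_that("tile mean identity and ordering invariance hold on random masks", {
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(runif(54 * 54) < runif(1, 0.2, 0.8), 54, 54)
    res <- cv_of_ccfa(m, grid = 18)   # 54 = 18 * 3, no trim
    expect_equal(res$trim_px, 0)
    expect_equal(mean(res$tile_ratios) * 100, ccfa_ratio(m), tolerance = 1e-12)
    # cv is a symmetric function of the tiles
    shuffled <- sample(res$tile_ratios)
    expect_equal(sd(shuffled) / mean(shuffled), res$cv, tolerance = 1e-12)
  }
})

test_that("impaired-flow rule uses strict < on CCFA and >= on CV", {
  expect_true(classify_impaired(58.4, 0.174))    # DR group means
  expect_false(classify_impaired(69.1, 0.124))   # control group means
  expect_false(classify_impaired(65.9, 0.200))   # boundary: strict <
  expect_true(classify_impaired(65.8, 0.140))    # boundary: >= on CV
})
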