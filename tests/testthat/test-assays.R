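test_that("analytic Gaussian crossing solves the density equality", {
  expect_equal(gaussianCrossing(10, 2, 20, 2), 15)
  x <- gaussianCrossing(10, 1, 20, 3)
  expect_equal(dnorm(x, 10, 1), dnorm(x, 20, 3), tolerance = 1e-9)
  expect_true(x > 10 && x < 20)
})

test_that("KDE threshold recovers the Gaussian crossing", {
  set.seed(1)
  ctrl <- rnorm(5000, 10, 2)
  trt <- rnorm(5000, 20, 2)
  thr <- densityCrossingThreshold(ctrl, trt)
  expect_lt(abs(thr - 15), 0.3)

  ctrl2 <- rnorm(5000, 10, 1)
  trt2 <- rnorm(5000, 20, 3)
  thr2 <- densityCrossingThreshold(ctrl2, trt2)
  expect_lt(abs(thr2 - gaussianCrossing(10, 1, 20, 3)), 0.5)

  # identical samples: KS cannot reject, no separable populations
  expect_error(densityCrossingThreshold(ctrl, ctrl), "no separable")
  expect_error(densityCrossingThreshold(trt, ctrl), "crossing")
  expect_error(densityCrossingThreshold(rnorm(10), rnorm(10, 5)), "30")
})

test_that("threshold moves up (weakly) when the treated sample shifts up", {
  set.seed(2)
  ctrl <- rnorm(2000, 10, 2)
  trt <- rnorm(2000, 16, 2)
  t1 <- densityCrossingThreshold(ctrl, trt)
  t2 <- densityCrossingThreshold(ctrl, trt + 2)
  expect_gte(t2, t1)
})

test_that("senescent fraction counts blue objects above threshold", {
  obj <- data.frame(
    condition = rep(c("control", "treated"), each = 4),
    replicate = "r1",
    green = c(1, 2, 3, 4, 10, 20, 2, 3),
    is_blue = TRUE)
  expect_equal(senescentFraction(obj, 100)$percent, c(0, 0))
  half <- senescentFraction(obj, 5)
  expect_equal(half$percent[half$condition == "treated"], 50)
  # non-increasing in the threshold
  f1 <- senescentFraction(obj, 1.5)$percent
  f2 <- senescentFraction(obj, 5)$percent
  expect_true(all(f2 <= f1))
  expect_error(senescentFraction(obj[0, ], 5), "blue")
})

test_that("planted mixture fraction is recovered from the KDE threshold", {
  mix <- simulateCellIntensities(10000, senescentFraction = 0.3, seed = 9)
  ctrl <- mix$green[mix$condition == "control"]
  trt <- mix$green[mix$condition == "treated"]
  thr <- densityCrossingThreshold(ctrl, trt)
  frac <- senescentFraction(mix, thr)
  got <- frac$percent[frac$condition == "treated"]
  expect_lt(abs(got - 30), 2)
})

test_that("ddCt chain matches hand computation and shift invariance", {
  ct <- data.frame(
    condition = c("control", "treated"),
    replicate = "r1",
    ct_target = c(19, 20),
    ct_ref1 = c(18, 18),
    ct_ref2 = c(18, 22))
  out <- ddct(ct, "control")
  # calibrator dCt = 1; treated dCt = 20 - 20 = 0; ddCt = -1 -> 2
  expect_equal(out$rel_expr, c(1, 2))

  shifted <- ct
  shifted[2, c("ct_target", "ct_ref1", "ct_ref2")] <-
    shifted[2, c("ct_target", "ct_ref1", "ct_ref2")] + 3.7
  expect_equal(ddct(shifted, "control")$rel_expr, out$rel_expr)

  expect_error(ddct(ct[, -3], "control"), "lacks")
  expect_error(ddct(ct, "missing"), "absent")
})

test_that("paired Wilcoxon is exact and matches the sign-permutation oracle", {
  # six positive, tie-free differences: two-sided exact p = 2 / 2^6
  a <- c(5.1, 6.4, 7.2, 8.9, 9.3, 10.8)
  b <- c(4.0, 5.1, 6.5, 7.2, 8.8, 9.1)
  expect_equal(pairedGroupTest(a, b), 0.03125)
  expect_equal(pairedGroupTest(a, a), 1)
  expect_error(pairedGroupTest(1:3, 2:4), "4 pairs")

  set.seed(12)
  for (i in 1:5) {
    n <- sample(5:8, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(pairedGroupTest(x, y), bruteWilcoxP(x - y),
                 tolerance = 1e-12)
  }
})

test_that("chi-squared outlier test removes at most one extreme value", {
  x <- c(10.1, 9.9, 10.0, 10.2, 9.95, 25)
  res <- chisqOutlierTest(x)
  expect_equal(res$value, 25)
  expect_lt(res$p, 0.05)
  expect_equal(removeOutlier(x), x[1:5])
  clean <- c(10.1, 9.9, 10.0, 10.2, 10.05)
  expect_equal(removeOutlier(clean), clean)
})
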