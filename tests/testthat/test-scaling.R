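test_that("subsample sizes are powers of two plus the full population", {
  fd <- iidDataset(100, rep(c("a", "b"), each = 20), seed = 1)
  cv <- subsampleCurve(fd, decoderSpec("svm", CGrid = 0.1), nResamples = 2,
                       seed = 1)
  expect_equal(curveSizes(cv), as.integer(c(1, 2, 4, 8, 16, 32, 64, 100)))
  # full-population size evaluated once, others nResamples times
  expect_equal(lengths(cv@accuracies),
               c(rep(2L, 7), 1L))
  expect_true(all(unlist(cv@accuracies) >= 0 & unlist(cv@accuracies) <= 1))
})

test_that("a single-neuron dataset yields the single size 1", {
  fd <- iidDataset(1, rep(c("a", "b"), each = 15), seed = 2)
  cv <- subsampleCurve(fd, decoderSpec("svm", CGrid = 0.1), nResamples = 2,
                       seed = 1)
  expect_equal(curveSizes(cv), 1L)
})

test_that("mean accuracy is non-decreasing in size for a decodable population", {
  m <- tunedPopulationModel(16, seed = 3, tuningAmplitude = 0.8, noiseSd = 0.4)
  fd <- zscoreFeatures(simulateTrialResponses(m, gratingPlan(8), seed = 1))
  cv <- subsampleCurve(fd, decoderSpec("svm", CGrid = c(1, 100),
                                       scheme = "holdout"),
                       nResamples = 3, seed = 2)
  acc <- meanAccuracy(cv)
  expect_true(all(diff(acc) > -0.08))   # monotone within Monte-Carlo error
  expect_gt(acc[length(acc)], acc[1])
})

test_that("noise-free generalized-logistic data are recovered to high precision", {
  truth <- c(a = 0.05, b = 0.8, c = 1 / 6)
  for (sizes in list(2^(0:7), 1:128)) {
    acc <- generalizedLogistic(sizes, truth["a"], truth["b"], truth["c"])
    f <- fitParams(fitAccuracyCurve(accuracyCurve(sizes, acc)))
    expect_lt(max(abs(c(f$a, f$b, f$c) / truth - 1)), 1e-3)
    expect_lt(f$residual, 1e-10)
  }
})

test_that("fitted parameters always satisfy the printed constraints", {
  withr::with_seed(9, {
    for (r in 1:20) {
      y <- pmin(1, pmax(0, sort(runif(8, 0.1, 1)) + rnorm(8, 0, 0.05)))
      f <- fitParams(fitAccuracyCurve(accuracyCurve(2^(0:7), y)))
      expect_gte(f$a, 0); expect_gte(f$b, 0)
      expect_lte(f$b, 1); expect_gte(f$c, 0)
    }
  })
})

test_that("a saturated curve fits accuracy 1 with negligible residual", {
  cv <- fitAccuracyCurve(accuracyCurve(2^(0:6), rep(1, 7)))
  expect_lt(fitParams(cv)$residual, 1e-8)
  expect_equal(extrapolateAccuracy(cv, c(1, 50, 1e4)), rep(1, 3),
               tolerance = 1e-4)
})

test_that("extrapolation evaluates the generalized logistic and is monotone", {
  # hand substitution: n = 0, b = 1, c = 1/6 -> (1 - 1/6)/2 + 1/6
  expect_equal(generalizedLogistic(0, 1, 1, 1 / 6), 0.5833333, tolerance = 1e-6)
  # hand evaluation at n = 128
  a <- 0.03; b <- 0.7; c <- 0.125
  expect_equal(generalizedLogistic(128, a, b, c),
               (1 - c) / (1 + exp(-a * 128))^b + c)
  # limit 1 as n grows, monotone for a > 0
  nseq <- c(0, 1, 2, 4, 8, 64, 512, 5000)
  v <- generalizedLogistic(nseq, 0.05, 0.8, 1 / 6)
  expect_true(all(diff(v) > 0))
  expect_equal(v[length(v)], 1, tolerance = 1e-6)
  # unfitted curve cannot be extrapolated
  expect_error(extrapolateAccuracy(accuracyCurve(2^(0:3), rep(0.5, 4)), 128),
               "unfitted")
})

test_that("noisy accuracies still give calibrated extrapolation at n = 128", {
  truth <- generalizedLogistic(1:128, 0.05, 0.8, 1 / 6)
  ok <- withr::with_seed(11, replicate(100, {
    y <- pmin(1, pmax(0, truth + rnorm(128, 0, 0.02)))
    f <- fitAccuracyCurve(accuracyCurve(1:128, y))
    abs(extrapolateAccuracy(f, 128) - truth[128]) <= 0.05
  }))
  expect_gte(mean(ok), 0.95)
})
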