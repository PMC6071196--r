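test_that("balanced split takes floor(0.8 x smallest class) per class", {
  labs <- rep(c("a", "b", "c"), c(100, 60, 20))
  fd <- iidDataset(2, labs, seed = 1)
  sp <- balancedTrainSplit(fd, seed = 3)
  expect_equal(length(sp$train), 3 * 16)
  expect_equal(length(sp$test), 180 - 48)
  expect_true(all(table(labs[sp$train]) == 16))
  # partition property
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labs))
  # balanced sizes {10, 10}
  sp2 <- balancedTrainSplit(iidDataset(2, rep(c("a", "b"), each = 10)), seed = 1)
  expect_equal(length(sp2$train), 16)
  expect_equal(length(sp2$test), 4)
})

test_that("random split uses the stated fraction and partitions the samples", {
  fd <- iidDataset(2, rep(c("a", "b"), 300), seed = 2)
  sp <- randomSplit(fd, seed = 1)
  expect_equal(length(sp$train), 480)
  expect_equal(length(sp$test), 120)
  expect_length(intersect(sp$train, sp$test), 0)
  sp2 <- randomSplit(iidDataset(2, rep(c("a", "b"), 5)), seed = 2)
  expect_equal(lengths(sp2[c("train", "test")]), c(train = 8, test = 2))
})

test_that("C selection breaks ties toward the smaller C and honors degenerate grids", {
  # widely separable two-class data: all C reach accuracy 1 -> smallest wins
  labs <- rep(c("a", "b"), 30)
  withr::with_seed(2, x2 <- rbind(ifelse(labs == "a", -10, 10) + rnorm(60)))
  fd <- featureDataset(x2, labs)
  spec <- decoderSpec("svm")
  expect_equal(selectRegularization(fd, spec, seed = 1), min(spec@CGrid))
  oneC <- decoderSpec("svm", CGrid = 10)
  expect_equal(selectRegularization(fd, oneC, seed = 1), 10)
})

test_that("heavily regularized C is preferred when n_features >> n_train with weak signal", {
  withr::with_seed(7, {
    labs <- rep(c("a", "b"), each = 20)
    x <- matrix(rnorm(200 * 40), 200, 40)
    x[1, ] <- x[1, ] + ifelse(labs == "a", -0.3, 0.3)
  })
  fd <- featureDataset(x, labs, zscored = TRUE)
  chosen <- selectRegularization(fd, decoderSpec("svm"), seed = 2)
  expect_lt(chosen, max(decoderSpec("svm")@CGrid))
})

test_that("decoding separable classes reaches perfect accuracy with both classifiers", {
  labs <- rep(c("a", "b", "c"), each = 40)
  withr::with_seed(3, {
    mu <- matrix(rnorm(3 * 6, 0, 4), 3)
    x <- t(mu[as.integer(factor(labs)), ] + matrix(rnorm(120 * 6, 0, 0.1), 120))
  })
  fd <- zscoreFeatures(featureDataset(x, labs))
  for (cl in c("svm", "mlr")) {
    r <- decode(fd, decoderSpec(cl), seed = 1)
    expect_equal(accuracy(r), 1)
    expect_s4_class(r, "DecodingResult")
  }
})

test_that("indistinguishable classes decode at chance", {
  accs <- vapply(1:4, function(s)
    accuracy(decode(iidDataset(16, rep(c("a", "b"), each = 60), seed = s),
                    decoderSpec("svm"), seed = s)), numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("label permutation destroys decodable structure down to chance", {
  m <- tunedPopulationModel(12, seed = 1, tuningAmplitude = 1)
  fd <- zscoreFeatures(simulateTrialResponses(m, gratingPlan(10), seed = 2))
  spec <- decoderSpec("svm", scheme = "holdout")
  expect_gt(accuracy(decode(fd, spec, seed = 1)), 0.5)
  accs <- vapply(1:4, function(s) {
    perm <- fd
    colData(perm)$label <- withr::with_seed(s, sample(sampleLabels(fd)))
    accuracy(decode(perm, spec, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 8), 0.06)
})

test_that("decoding is deterministic given (data, spec, seed)", {
  fd <- iidDataset(8, rep(letters[1:3], each = 30), seed = 4)
  r1 <- decode(fd, decoderSpec("svm"), seed = 11)
  r2 <- decode(fd, decoderSpec("svm"), seed = 11)
  expect_identical(confusionMatrix(r1), confusionMatrix(r2))
  expect_identical(chosenC(r1), chosenC(r2))
})

test_that("confusion matrix rows sum to per-class test counts and accuracy is its trace ratio", {
  labs <- rep(c("a", "b", "c"), c(50, 40, 30))
  fd <- iidDataset(6, labs, seed = 5)
  r <- decode(fd, decoderSpec("svm"), seed = 2)
  cm <- confusionMatrix(r)
  expect_equal(sum(cm), 120)                    # every sample tested once
  expect_equal(unname(rowSums(cm)), c(50, 40, 30))
  expect_equal(accuracy(r), sum(diag(cm)) / sum(cm))
  pc <- perClassAccuracy(r)
  expect_true(all(pc >= 0 & pc <= 1))
})

test_that("decode errors on degenerate label sets", {
  expect_error(decode(iidDataset(2, rep("a", 20)), decoderSpec("svm")),
               "2 classes")
})

test_that("the dual coordinate-descent SVM agrees with libsvm on well-posed problems", {
  skip_if_not_installed("e1071")
  withr::with_seed(6, {
    x <- matrix(rnorm(200 * 5), 200, 5)
    w <- c(2, -1, 0.5, 0, 1)
    y <- factor(ifelse(x %*% w > 0, "p", "q"))
  })
  fd <- featureDataset(t(x), as.character(y), zscored = TRUE)
  ours <- decode(fd, decoderSpec("svm", CGrid = 1, scheme = "holdout"),
                 seed = 1)
  sp <- randomSplit(fd, seed = 1)
  ref <- e1071::svm(x[sp$train, ], y[sp$train], kernel = "linear", cost = 1,
                    scale = FALSE)
  refAcc <- mean(predict(ref, x[sp$test, ]) == y[sp$test])
  expect_lt(abs(accuracy(ours) - refAcc), 0.05)
})
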