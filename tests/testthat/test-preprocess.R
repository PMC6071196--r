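mkRec <- function(f, rate = 30, ids = paste0("n", seq_len(nrow(f)))) {
  fluorescenceRecording(f, (seq_len(ncol(f)) - 1) / rate, ids, "X",
                        frameRate = rate)
}

test_that("dF/F of a constant trace is zero everywhere defined", {
  d <- computeDFF(mkRec(matrix(100, 2, 90)))
  expect_true(all(is.na(d[, 1])))
  expect_true(all(d[, -1] == 0))
})

test_that("dF/F of a step trace jumps to (150-100)/100 at the step", {
  f <- matrix(c(rep(100, 30), rep(150, 30)), 1, 60, byrow = TRUE)
  d <- computeDFF(mkRec(f))
  expect_equal(unname(d[1, 31]), 0.5)
  expect_equal(unname(d[1, 30]), 0)
})

test_that("dF/F of a ramp matches a brute-force windowed-mean oracle", {
  rate <- 30
  ts <- (0:89) / rate
  f <- matrix(100 + 10 * ts, 1)
  d <- computeDFF(mkRec(f, rate))
  i <- which(abs(ts - 2.0) < 1e-9)
  win <- which(ts >= 1.0 & ts < 2.0)        # the preceding 1 s
  f0 <- mean(f[1, win])
  expect_equal(unname(d[1, i]), (f[1, i] - f0) / f0)
})

test_that("dF/F is invariant to scaling a neuron's trace by a positive constant", {
  withr::with_seed(1, f <- matrix(100 + cumsum(rnorm(120, 0, 0.5)), 1))
  d1 <- computeDFF(mkRec(f))
  d2 <- computeDFF(mkRec(7.3 * f))
  expect_equal(d1, d2)
})

test_that("dF/F rejects non-positive baselines and too-short windows", {
  expect_error(computeDFF(mkRec(matrix(0, 1, 60))), "positive")
  expect_error(computeDFF(mkRec(matrix(100, 1, 60)), baselineWindowS = 0.01),
               "2 frames")
})

test_that("epoch segmentation follows the floor(duration/interval) discard rule", {
  rate <- 30
  nF <- 40 * rate
  dff <- matrix(0.2, 2, nF)
  ts <- (seq_len(nF) - 1) / rate
  counts <- function(dur) {
    ncol(segmentClassEpochs(dff, ts,
                            data.frame(start_s = 0, stop_s = dur, class = "x")))
  }
  expect_equal(counts(35), 3)     # 5 s discarded
  expect_equal(counts(10), 1)     # exact boundary kept
  expect_error(counts(9.9), "no complete intervals")  # < 10 s discarded
  # multi-epoch closed form on randomized tables
  withr::with_seed(4, durs <- runif(5, 0, 8))
  starts <- cumsum(c(0, durs[-5] + 0.5))
  ep <- data.frame(start_s = starts, stop_s = starts + durs, class = "x")
  expected <- sum(floor(durs / 2))
  got <- tryCatch(ncol(segmentClassEpochs(dff, ts, ep, intervalS = 2)),
                  error = function(e) 0L)
  expect_equal(got, expected)
})

test_that("epoch segmentation features equal the interval mean and carry labels", {
  rate <- 30
  ts <- (0:(30 * rate - 1)) / rate
  withr::with_seed(2, dff <- matrix(rnorm(2 * length(ts)), 2))
  ep <- data.frame(start_s = c(0, 12), stop_s = c(12, 30),
                   class = c("a", "b"))
  fd <- segmentClassEpochs(dff, ts, ep, intervalS = 10)
  expect_equal(ncol(fd), 2)
  expect_equal(sampleLabels(fd), c("a", "b"))
  mids <- ts + 1 / (2 * rate)
  oracle <- rowMeans(dff[, mids >= 12 & mids < 22])
  expect_equal(unname(featureMatrix(fd)[, 2]), unname(oracle))
  expect_error(segmentClassEpochs(dff, ts,
    data.frame(start_s = c(0, 5), stop_s = c(10, 20), class = "x")),
    "non-overlapping")
})

test_that("grating segmentation yields one direction-labeled sample per trial", {
  m <- labelIndependentModel(3)
  sim <- simulateRecording(m, defaultSessionSpecs()$A, seed = 2)
  dff <- computeDFF(sim$recording)
  fd <- segmentGratingTrials(dff, timestamps(sim$recording), sim$trials)
  expect_equal(ncol(fd), 600)
  expect_true(all(table(sampleLabels(fd)) == 75))   # 15 repeats x 5 tfs
  expect_equal(sort(unique(colData(fd)$temporal_freq_hz)),
               gratingTemporalFrequencies())
})

test_that("grating trial features equal the brute-force window mean", {
  rate <- 30
  ts <- (0:299) / rate
  withr::with_seed(3, dff <- matrix(rnorm(300), 1))
  dff[1, 61:120] <- 0.2   # constant over the trial window [2, 4)
  tr <- data.frame(onset_s = 2, duration_s = 2, direction_deg = 45,
                   temporal_freq_hz = 2)
  fd <- segmentGratingTrials(dff, ts, tr)
  expect_equal(unname(featureMatrix(fd)[1, 1]), 0.2)
  expect_equal(sampleLabels(fd), "45")
  # hand-written 60-frame oracle
  tr2 <- data.frame(onset_s = 5, duration_s = 2, direction_deg = 90,
                    temporal_freq_hz = 1)
  fd2 <- segmentGratingTrials(dff, ts, tr2)
  mids <- ts + 1 / (2 * rate)
  expect_equal(unname(featureMatrix(fd2)[1, 1]),
               mean(dff[1, mids >= 5 & mids < 7]))
  expect_error(segmentGratingTrials(dff, ts,
    data.frame(onset_s = 9.5, duration_s = 2, direction_deg = 0,
               temporal_freq_hz = 1)), "past the end")
})

test_that("intersectNeurons restricts to the sorted common identifiers", {
  mk <- function(ids) featureDataset(matrix(seq_along(ids), length(ids), 4),
                                     rep("a", 4), neuronIds = ids)
  out <- intersectNeurons(list(mk(c("1", "2", "3")), mk(c("3", "2", "4"))))
  expect_equal(rownames(out[[1]]), c("2", "3"))
  expect_equal(rownames(out[[2]]), c("2", "3"))
  # identical sets unchanged (sorted)
  out2 <- intersectNeurons(list(mk(c("a", "b")), mk(c("a", "b"))))
  expect_equal(rownames(out2[[1]]), c("a", "b"))
  # three-way staged overlap matches the set oracle
  ids <- list(c("1", "2", "3", "5"), c("2", "3", "4", "5"), c("5", "3", "9"))
  out3 <- intersectNeurons(lapply(ids, mk))
  expect_equal(rownames(out3[[3]]), sort(Reduce(intersect, ids)))
  expect_error(intersectNeurons(list(mk("1"), mk("2"))), "common")
})

test_that("z-scoring uses the population-SD convention and is idempotent", {
  fd <- featureDataset(matrix(c(1, 2, 3), 1, 3), c("a", "b", "c"))
  z <- zscoreFeatures(fd)
  expect_equal(unname(featureMatrix(z)[1, ]),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  z2 <- zscoreFeatures(z)
  expect_equal(featureMatrix(z2), featureMatrix(z), tolerance = 1e-12)
  expect_equal(sampleLabels(z2), sampleLabels(fd))
  expect_true(isZscored(z))
  # per-neuron moments after z-scoring
  withr::with_seed(5, fd2 <- featureDataset(matrix(rnorm(60), 3), rep("a", 20)))
  x <- featureMatrix(zscoreFeatures(fd2))
  expect_true(all(abs(rowMeans(x)) < 1e-9))
  expect_true(all(abs(rowMeans(x^2) - 1) < 1e-9))
})

test_that("constant neurons are mapped to zero rows with a warning", {
  fd <- featureDataset(rbind(c(1, 1, 1), c(1, 2, 3)), c("a", "b", "c"))
  expect_warning(z <- zscoreFeatures(fd), "zero variance")
  expect_true(all(featureMatrix(z)[1, ] == 0))
})
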