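test_that("tuning curve hits its defining constraints exactly", {
  r <- makeTuningResponse(c(0, 90, 180, 270), 0, 2, 1.5, dsiFactor = 0.3)
  expect_equal(r[1], 1.5)              # peak at preferred
  expect_equal(r[3], 0.3 * 1.5)        # null = dsiFactor x preferred
  expect_equal(r[2], r[4])             # symmetric orthogonals
  # orthogonal response decreases with concentration
  ro <- vapply(c(0.5, 1, 2, 4), function(k)
    makeTuningResponse(90, 0, k, 1, 0.3), numeric(1))
  expect_true(all(diff(ro) < 0))
})

test_that("symmetric tuning (dsiFactor = 1) gives response(theta) = response(theta + 180)", {
  th <- seq(0, 315, by = 45)
  r <- makeTuningResponse(th, 30, 3, 1, dsiFactor = 1)
  r180 <- makeTuningResponse((th + 180) %% 360, 30, 3, 1, dsiFactor = 1)
  expect_equal(r, r180)
})

test_that("near-delta tuning with dsiFactor 0 is nonzero only at the preferred direction", {
  r <- makeTuningResponse(gratingDirections(), 90, 200, 1, dsiFactor = 0)
  expect_equal(r[gratingDirections() == 90], 1)
  expect_true(all(r[gratingDirections() != 90] < 1e-8))
})

test_that("flat tuning (zero concentration) returns the amplitude everywhere", {
  expect_equal(makeTuningResponse(c(5, 111, 290), 0, 0, 0.7, 0.5),
               rep(0.7, 3))
})

test_that("zero-activity model yields constant fluorescence at baseline", {
  m <- labelIndependentModel(3, baseMean = 0, noiseSd = 0, measurementSd = 0)
  s <- sessionSpec("B", data.frame(class = "spontaneous", duration_s = 20))
  sim <- simulateRecording(m, s, seed = 1)
  expect_true(all(fluorescence(sim$recording) == 100))
})

test_that("default grating session has 600 trials spanning 1800 s, 15 per condition", {
  m <- labelIndependentModel(2)
  sim <- simulateRecording(m, defaultSessionSpecs()$A, seed = 3)
  tr <- sim$trials
  expect_equal(nrow(tr), 600)
  ge <- sim$epochs[sim$epochs$class == "drifting_gratings", ]
  expect_equal(ge$stop_s - ge$start_s, 1800)
  counts <- table(tr$direction_deg, tr$temporal_freq_hz)
  expect_true(all(counts == 15))
  expect_equal(dim(counts), c(8L, 5L))
  # randomized order: not sorted by condition
  expect_gt(length(rle(tr$direction_deg)$lengths), 100)
})

test_that("simulation is bit-identical under the same seed and differs otherwise", {
  m <- tunedPopulationModel(4, seed = 2, sharedGainSd = 0.3)
  s <- sessionSpec("B", data.frame(class = c("spontaneous", "natural_movies"),
                                   duration_s = c(15, 15)))
  a <- simulateRecording(m, s, seed = 7)
  b <- simulateRecording(m, s, seed = 7)
  expect_identical(fluorescence(a$recording), fluorescence(b$recording))
  d <- simulateRecording(m, s, seed = 8)
  expect_false(identical(fluorescence(a$recording), fluorescence(d$recording)))
})

test_that("invalid session plans are rejected", {
  expect_error(sessionSpec("A", data.frame(class = "spontaneous",
                                           duration_s = -5)),
               "duration")
  expect_error(sessionSpec("A", data.frame(class = "spontaneous",
                                           duration_s = 10),
                           gratingPlan = gratingPlan(nRepeats = 0)),
               "nRepeats")
  expect_error(sessionSpec("A", data.frame(class = "spontaneous",
                                           duration_s = 10),
                           frameRate = 0),
               "frameRate")
})

test_that("trial noise correlations vanish without shared gain and grow with it", {
  singleCond <- gratingPlan(nRepeats = 500, directions = 0,
                            temporalFrequencies = 1)
  noiseCor <- function(sg) {
    m <- populationModel(2, matrix(1, 6, 2,
                                   dimnames = list(stimulusClasses(), NULL)),
                         tuningAmplitude = 1, noiseSd = 0.2,
                         sharedGainSd = sg)
    x <- featureMatrix(simulateTrialResponses(m, singleCond, seed = 5))
    cor(x[1, ], x[2, ])
  }
  expect_lt(abs(noiseCor(0)), 0.1)
  grid <- vapply(c(0, 0.3, 0.6, 1), noiseCor, numeric(1))
  expect_true(all(diff(grid) > 0))
})

test_that("label-independent mode has identical class means and no tuning", {
  m <- labelIndependentModel(5)
  expect_true(all(m@classMeans == m@classMeans[1, 1]))
  expect_true(all(m@tuningAmplitude == 0))
})
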