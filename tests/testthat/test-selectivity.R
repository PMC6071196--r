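gridTable <- function(values) {
  matrix(values, 8, 5,
         dimnames = list(gratingDirections(), gratingTemporalFrequencies()))
}

test_that("condition means average the repeats of each of the 40 conditions", {
  m <- labelIndependentModel(3, baseMean = 0, noiseSd = 0)
  fd <- simulateTrialResponses(m, gratingPlan(15), seed = 1, noise = FALSE)
  # constant response: every cell equals it
  assay(fd, "features")[] <- 0.4
  cm <- conditionMeans(fd)
  expect_equal(dim(cm), c(3L, 8L, 5L))      # 40 cells per neuron
  expect_true(all(cm == 0.4))
  # hand-listed repeats for one condition match the brute-force mean
  cd <- colData(fd)
  idx <- which(cd$direction_deg == 90 & cd$temporal_freq_hz == 2)
  expect_length(idx, 15)
  vals <- seq(0.1, 0.3, length.out = 15)
  assay(fd, "features")[1, idx] <- vals
  expect_equal(conditionMeans(fd)[1, "90", "2"], mean(vals))
})

test_that("missing conditions are reported by cell", {
  fd <- featureDataset(matrix(1, 1, 2), c("0", "45"),
                       colData = list(direction_deg = c(0, 45),
                                      temporal_freq_hz = c(1, 2)))
  expect_error(conditionMeans(fd), "no trials")
})

test_that("preferred condition is the argmax with lowest-direction, lowest-tf ties", {
  tb <- gridTable(rep(0, 40)); tb["135", "4"] <- 1
  expect_equal(unname(preferredCondition(tb)), c(135, 4))
  # all-equal table -> (0 deg, lowest tf)
  expect_equal(unname(preferredCondition(gridTable(rep(0.2, 40)))), c(0, 1))
  # randomized tables match an exhaustive-scan oracle
  withr::with_seed(7, for (r in 1:20) {
    tb <- gridTable(rnorm(40))
    pc <- preferredCondition(tb)
    expect_equal(tb[as.character(pc["direction"]), as.character(pc["tf"])],
                 max(tb))
  })
})

test_that("OSI/DSI formulas reproduce hand-substituted values", {
  # perfect selectivity
  tb <- gridTable(rep(0, 40)); tb["0", "1"] <- 1
  s <- computeOsiDsi(tb)
  expect_equal(s$OSI, 1); expect_equal(s$DSI, 1)
  # flat tuning
  s0 <- computeOsiDsi(gridTable(rep(0.3, 40)))
  expect_equal(s0$OSI, 0); expect_equal(s0$DSI, 0)
  # Rpref 0.3, Rorth 0.1, Rnull -0.1 -> OSI 0.5, DSI 2
  tb2 <- gridTable(rep(-5, 40))
  tb2["0", "1"] <- 0.3; tb2["90", "1"] <- 0.1; tb2["270", "1"] <- 0.1
  tb2["180", "1"] <- -0.1
  s2 <- computeOsiDsi(tb2)
  expect_equal(s2$OSI, 0.5)
  expect_equal(s2$DSI, 2)
  expect_equal(s2$Rpref, 0.3); expect_equal(s2$Rorth, 0.1)
  expect_equal(s2$Rnull, -0.1)
  # zero denominator -> undefined
  tb3 <- gridTable(rep(0, 40)); tb3["0", "1"] <- 0.2; tb3["180", "1"] <- -0.2
  expect_true(is.na(computeOsiDsi(tb3)$DSI))
})

test_that("noise-free simulated tuning matches the closed-form indices to 1e-6", {
  m <- tunedPopulationModel(8, seed = 3, tuningAmplitude = 0.4)
  fd <- simulateTrialResponses(m, gratingPlan(2), seed = 1, noise = FALSE)
  st <- selectivityTable(fd)
  theory <- t(vapply(seq_len(8), function(i) gridTheoryOsiDsi(m, i),
                     numeric(2)))
  expect_equal(st$OSI, unname(theory[, "OSI"]), tolerance = 1e-6)
  expect_equal(st$DSI, unname(theory[, "DSI"]), tolerance = 1e-6)
})

test_that("dsiFactor 1 forces DSI 0 and isotropic tuning forces OSI 0", {
  mSym <- populationModel(2, matrix(1, 6, 2,
                                    dimnames = list(stimulusClasses(), NULL)),
                          tuningAmplitude = 0.5, dsiFactor = 1,
                          tuningWidth = 2)
  stSym <- selectivityTable(simulateTrialResponses(mSym, gratingPlan(1),
                                                   seed = 1, noise = FALSE))
  expect_equal(stSym$DSI, c(0, 0), tolerance = 1e-12)
  mIso <- populationModel(2, matrix(1, 6, 2,
                                    dimnames = list(stimulusClasses(), NULL)),
                          tuningAmplitude = 0.5, tuningWidth = 0)
  stIso <- selectivityTable(simulateTrialResponses(mIso, gratingPlan(1),
                                                   seed = 1, noise = FALSE))
  expect_equal(stIso$OSI, c(0, 0), tolerance = 1e-12)
})

test_that("the exclusion rule keeps exactly the closed interval [0, 2]", {
  ex <- applyExclusions(c(-0.1, 0.5, 2.5, 2.0, 0))
  expect_equal(ex$kept, c(0.5, 2.0, 0))
  expect_equal(ex$nExcludedLow, 1)
  expect_equal(ex$nExcludedHigh, 1)
  expect_equal(applyExclusions(c(0.2, 1.5))$kept, c(0.2, 1.5))
  allOut <- applyExclusions(c(-3, 5, NA))
  expect_length(allOut$kept, 0)
  expect_equal(allOut$nExcludedUndefined, 1)
})

test_that("group averages report mean, SEM and degenerate groups", {
  tbl <- data.frame(neuron_id = as.character(1:3), pref_dir = 0, pref_tf = 1,
                    Rpref = 1, Rorth = 0, Rnull = 0,
                    OSI = c(0.2, 0.4, 0.9), DSI = c(0.1, 0.3, 3),
                    excluded_osi = FALSE, excluded_dsi = c(FALSE, FALSE, TRUE))
  g <- groupAverage(tbl, c("g1", "g1", "g2"), "OSI")
  expect_equal(g$mean[g$group == "g1"], 0.3)
  expect_equal(g$sem[g$group == "g1"], 0.1, tolerance = 1e-9)
  # single-neuron group flagged with zero-width SEM
  expect_true(g$degenerate[g$group == "g2"])
  expect_equal(g$sem[g$group == "g2"], 0)
  # excluded values are dropped: g2 has no usable DSI
  gd <- groupAverage(tbl, c("g1", "g1", "g2"), "DSI")
  expect_equal(gd$n[gd$group == "g2"], 0)
  expect_true(is.na(gd$mean[gd$group == "g2"]))
})

test_that("imaging depths map onto the four canonical groups", {
  expect_equal(as.character(depthGroup(c(175, 300, 350, 435))),
               c("175", "265-300", "325-350", "365-435"))
  expect_equal(as.character(depthGroup(c(265, 275, 325, 335, 365, 375))),
               c("265-300", "265-300", "325-350", "325-350",
                 "365-435", "365-435"))
})
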