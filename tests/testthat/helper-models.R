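## Shared builders for the test suite. Everything is generated in code; no
## fixture files.

suppressMessages(library(SummarizedExperiment))

## stimulus-class feature dataset from the full preprocessing pipeline
classPipelineDataset <- function(model, specs, seed) {
  dsets <- lapply(specs, function(s) {
    sim <- simulateRecording(model, s, seed = seed)
    dff <- computeDFF(sim$recording)
    segmentClassEpochs(dff, timestamps(sim$recording), sim$epochs,
                       sessionId = sessionId(sim$recording))
  })
  zscoreFeatures(combineFeatureDatasets(dsets))
}

## direction feature dataset from the grating session
directionPipelineDataset <- function(model, seed, spec = defaultSessionSpecs()$A) {
  sim <- simulateRecording(model, spec, seed = seed)
  dff <- computeDFF(sim$recording)
  zscoreFeatures(segmentGratingTrials(dff, timestamps(sim$recording),
                                      sim$trials, sessionId = "A"))
}

## 2-neuron dataset where class information lives only in the sign of the
## pairwise correlation: class A pairs x2 = x1, class B pairs x2 = -x1,
## x1 = +/-1, plus small iid jitter. Class means are identical (zero).
correlationCodedDataset <- function(nPerClass = 400, seed = 1, jitter = 0.05) {
  withr::with_seed(seed, {
    x1 <- sample(c(-1, 1), 2 * nPerClass, replace = TRUE)
    cls <- rep(c("A", "B"), each = nPerClass)
    x2 <- ifelse(cls == "A", x1, -x1)
    feats <- rbind(x1, x2) +
      matrix(stats::rnorm(4 * nPerClass, 0, jitter), 2, 2 * nPerClass)
  })
  featureDataset(feats, cls, neuronIds = c("n1", "n2"), zscored = TRUE)
}

## iid-Gaussian feature dataset (no structure at all)
iidDataset <- function(nNeurons, labels, seed = 1) {
  withr::with_seed(seed,
    x <- matrix(stats::rnorm(nNeurons * length(labels)), nNeurons))
  featureDataset(x, labels)
}

## closed-form OSI/DSI of a model neuron, evaluated on the 8-direction grid
## (independent oracle: direct evaluation of the tuning curve)
gridTheoryOsiDsi <- function(model, i) {
  r <- makeTuningResponse(gratingDirections(), model@prefDirection[i],
                          model@tuningWidth[i], model@tuningAmplitude[i],
                          model@dsiFactor[i])
  pref <- gratingDirections()[which.max(r)]
  at <- function(d) r[match(d %% 360, gratingDirections())]
  rp <- at(pref); ro <- mean(c(at(pref + 90), at(pref - 90))); rn <- at(pref + 180)
  c(OSI = (rp - ro) / (rp + ro), DSI = (rp - rn) / (rp + rn))
}
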