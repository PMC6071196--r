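#' @include popdecode-package.R
NULL

## ---------------------------------------------------------------------------
## Core data containers
## ---------------------------------------------------------------------------

#' FluorescenceRecording: raw fluorescence for one imaging session
#'
#' A \linkS4class{SummarizedExperiment} holding one session's raw fluorescence
#' matrix (neurons x frames, arbitrary units) under assay \code{"fluorescence"},
#' with per-frame acquisition timestamps (seconds, nominally 30 Hz) in
#' \code{colData()$timestamp} and stable neuron identifiers as rownames.
#' The session identifier lives in \code{metadata()$session_id}.
#'
#' @export
setClass("FluorescenceRecording", contains = "SummarizedExperiment")

setValidity("FluorescenceRecording", function(object) {
  msg <- character()
  if (!"fluorescence" %in% assayNames(object))
    msg <- c(msg, "assay 'fluorescence' is required")
  if (!"timestamp" %in% colnames(colData(object)))
    msg <- c(msg, "colData column 'timestamp' is required")
  else {
    ts <- colData(object)$timestamp
    if (length(ts) != ncol(object))
      msg <- c(msg, "one timestamp per frame is required")
    if (length(ts) > 1L && any(diff(ts) <= 0))
      msg <- c(msg, "timestamps must be strictly increasing")
  }
  if (is.null(rownames(object)))
    msg <- c(msg, "neuron identifiers (rownames) are required")
  if ("fluorescence" %in% assayNames(object) &&
      anyNA(assay(object, "fluorescence")))
    msg <- c(msg, "raw fluorescence must not contain NA")
  if ("fluorescence" %in% assayNames(object) &&
      any(assay(object, "fluorescence") < 0))
    msg <- c(msg, "raw fluorescence must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a FluorescenceRecording
#'
#' @param fluorescence numeric matrix, neurons x frames, non-negative.
#' @param timestamps numeric vector of frame times in seconds, strictly
#'   increasing, one per frame.
#' @param neuronIds character or integer identifiers, one per neuron; must be
#'   stable across sessions so populations can be intersected.
#' @param sessionId session label, e.g. \code{"A"}.
#' @param frameRate nominal acquisition rate in Hz (metadata only).
#' @return A \linkS4class{FluorescenceRecording}.
#' @export
#' @examples
#' f <- matrix(100, 2, 90)
#' rec <- fluorescenceRecording(f, (0:89) / 30, c("n1", "n2"), "A")
#' rec
fluorescenceRecording <- function(fluorescence, timestamps, neuronIds,
                                  sessionId = NA_character_, frameRate = 30) {
  fluorescence <- as.matrix(fluorescence)
  rownames(fluorescence) <- as.character(neuronIds)
  se <- SummarizedExperiment(
    assays = list(fluorescence = fluorescence),
    colData = S4Vectors::DataFrame(timestamp = as.numeric(timestamps)),
    metadata = list(session_id = sessionId, frame_rate = frameRate))
  new("FluorescenceRecording", se)
}

#' FeatureDataset: labeled population feature vectors
#'
#' A \linkS4class{SummarizedExperiment} with assay \code{"features"}
#' (neurons x samples; each column is one population feature vector of mean
#' \eqn{\Delta F/F} values, z-scored per neuron after
#' \code{\link{zscoreFeatures}}). \code{colData()} carries per-sample
#' metadata: \code{label} (stimulus class or grating direction),
#' \code{window_start}/\code{window_stop} (seconds), and for grating datasets
#' \code{direction_deg} and \code{temporal_freq_hz}.
#' \code{metadata()$zscored} records whether z-scoring has been applied.
#'
#' @export
setClass("FeatureDataset", contains = "SummarizedExperiment")

setValidity("FeatureDataset", function(object) {
  msg <- character()
  if (!"features" %in% assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  if (!"label" %in% colnames(colData(object)))
    msg <- c(msg, "colData column 'label' is required")
  if (is.null(rownames(object)))
    msg <- c(msg, "neuron identifiers (rownames) are required")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureDataset
#'
#' @param features numeric matrix, neurons x samples.
#' @param labels per-sample labels (character); length \code{ncol(features)}.
#' @param neuronIds identifiers, one per neuron (defaults to
#'   \code{rownames(features)}).
#' @param windows optional two-column matrix / data.frame of sample windows
#'   \code{(start_s, stop_s)}.
#' @param colData optional extra per-sample columns (e.g.
#'   \code{direction_deg}, \code{temporal_freq_hz}, \code{session}).
#' @param zscored logical flag stored in \code{metadata()}.
#' @return A \linkS4class{FeatureDataset}.
#' @export
#' @examples
#' fd <- featureDataset(matrix(rnorm(20), 2, 10), rep(c("a", "b"), 5),
#'                      neuronIds = c("n1", "n2"))
#' fd
featureDataset <- function(features, labels, neuronIds = rownames(features),
                           windows = NULL, colData = NULL, zscored = FALSE) {
  features <- as.matrix(features)
  if (is.null(neuronIds))
    neuronIds <- paste0("neuron_", seq_len(nrow(features)))
  rownames(features) <- as.character(neuronIds)
  cd <- S4Vectors::DataFrame(label = as.character(labels))
  if (!is.null(windows)) {
    windows <- as.matrix(windows)
    cd$window_start <- as.numeric(windows[, 1])
    cd$window_stop <- as.numeric(windows[, 2])
  }
  if (!is.null(colData))
    for (nm in names(colData)) cd[[nm]] <- colData[[nm]]
  se <- SummarizedExperiment(assays = list(features = features), colData = cd,
                             metadata = list(zscored = isTRUE(zscored)))
  new("FeatureDataset", se)
}

## ---------------------------------------------------------------------------
## Synthetic-data model and session plan
## ---------------------------------------------------------------------------

#' PopulationModel: generative model of one neural population
#'
#' Parameters of the synthetic population: per-neuron baseline fluorescence,
#' per-class mean calcium-event amplitudes (rows = stimulus classes), circular
#' direction tuning (preferred direction, von Mises concentration, amplitude,
#' and a null-to-preferred response ratio \code{dsiFactor}), a per-tf gain
#' profile, private trial noise, and a rank-1 shared-gain factor that induces
#' controllable noise correlations. Fluorescence dynamics are governed by a
#' single-exponential calcium kernel (\code{calciumTau}, seconds) and additive
#' measurement noise.
#'
#' @slot nNeurons integer population size.
#' @slot baselineF per-neuron baseline fluorescence (a.u., > 0).
#' @slot classMeans matrix (classes x neurons) of mean calcium-event
#'   amplitudes in \eqn{\Delta F/F} units (peak fractional fluorescence change
#'   of one event); rownames are the class names.
#' @slot prefDirection,tuningWidth,tuningAmplitude,dsiFactor per-neuron
#'   direction-tuning parameters (degrees; concentration >= 0; amplitude >= 0;
#'   null/preferred ratio in `[0, 1]`).
#' @slot tfProfile multiplicative gain per temporal frequency (named numeric,
#'   shared across neurons).
#' @slot noiseSd per-neuron private trial noise SD (>= 0).
#' @slot sharedGainSd SD of the latent shared gain (>= 0; 0 = independent).
#' @slot gainLoadings per-neuron loadings on the shared gain.
#' @slot measurementSd additive fluorescence measurement noise SD (a.u.).
#' @slot calciumTau calcium kernel decay time constant (s).
#' @slot eventRate per-neuron rate (Hz) of spontaneous/evoked calcium events
#'   within stimulus-class epochs.
#' @slot blockS duration (s) of the shared-gain blocks: the latent gain is
#'   redrawn every \code{blockS} seconds and multiplies the amplitudes of
#'   concurrent events across neurons.
#' @export
setClass("PopulationModel",
  representation(nNeurons = "integer", baselineF = "numeric",
                 classMeans = "matrix", prefDirection = "numeric",
                 tuningWidth = "numeric", tuningAmplitude = "numeric",
                 dsiFactor = "numeric", tfProfile = "numeric",
                 noiseSd = "numeric", sharedGainSd = "numeric",
                 gainLoadings = "numeric", measurementSd = "numeric",
                 calciumTau = "numeric", blockS = "numeric",
                 eventRate = "numeric"))

setValidity("PopulationModel", function(object) {
  n <- object@nNeurons
  msg <- character()
  chk <- function(x, nm) if (length(x) != n)
    sprintf("'%s' must have one value per neuron", nm) else character()
  msg <- c(msg, chk(object@baselineF, "baselineF"),
           chk(object@prefDirection, "prefDirection"),
           chk(object@tuningWidth, "tuningWidth"),
           chk(object@tuningAmplitude, "tuningAmplitude"),
           chk(object@dsiFactor, "dsiFactor"),
           chk(object@noiseSd, "noiseSd"),
           chk(object@gainLoadings, "gainLoadings"))
  if (ncol(object@classMeans) != n)
    msg <- c(msg, "classMeans must have one column per neuron")
  if (is.null(rownames(object@classMeans)))
    msg <- c(msg, "classMeans must have class names as rownames")
  if (!all(is.finite(object@classMeans)))
    msg <- c(msg, "classMeans must be finite")
  if (any(object@baselineF <= 0)) msg <- c(msg, "baselineF must be > 0")
  if (any(object@tuningWidth < 0)) msg <- c(msg, "tuningWidth must be >= 0")
  if (any(object@tuningAmplitude < 0))
    msg <- c(msg, "tuningAmplitude must be >= 0")
  if (any(object@dsiFactor < 0 | object@dsiFactor > 1))
    msg <- c(msg, "dsiFactor must be in `[0, 1]`")
  if (any(object@noiseSd < 0) || object@sharedGainSd < 0 ||
      object@measurementSd < 0)
    msg <- c(msg, "all noise SDs must be >= 0")
  if (object@calciumTau < 0) msg <- c(msg, "calciumTau must be >= 0")
  if (object@blockS <= 0) msg <- c(msg, "blockS must be > 0")
  if (length(object@eventRate) != n || any(object@eventRate < 0))
    msg <- c(msg, "eventRate must have one non-negative value per neuron")
  if (length(msg)) msg else TRUE
})

#' SessionSpec: layout of one simulated imaging session
#'
#' @slot sessionId one of \code{"A"}, \code{"B"}, \code{"C"}.
#' @slot epochPlan data.frame with columns \code{class} and \code{duration_s}
#'   giving the ordered non-grating stimulus epochs.
#' @slot gratingPlan empty list, or (session A) a list with elements
#'   \code{nRepeats}, \code{durationOn}, \code{durationGray},
#'   \code{directions}, \code{temporalFrequencies}; the drifting-grating
#'   epoch (trials in randomized order) is placed before the epochs of
#'   \code{epochPlan}.
#' @slot frameRate acquisition rate in Hz.
#' @export
setClass("SessionSpec",
  representation(sessionId = "character", epochPlan = "data.frame",
                 gratingPlan = "list", frameRate = "numeric"))

setValidity("SessionSpec", function(object) {
  msg <- character()
  ep <- object@epochPlan
  if (nrow(ep) && (!all(c("class", "duration_s") %in% names(ep)) ||
                   any(ep$duration_s <= 0)))
    msg <- c(msg, "epochPlan needs columns class, duration_s with durations > 0")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  gp <- object@gratingPlan
  if (length(gp)) {
    if (is.null(gp$nRepeats) || gp$nRepeats <= 0)
      msg <- c(msg, "gratingPlan$nRepeats must be > 0")
    if (is.null(gp$durationOn) || gp$durationOn <= 0 ||
        is.null(gp$durationGray) || gp$durationGray < 0)
      msg <- c(msg, "gratingPlan durations must be positive")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Decoder configuration and results
## ---------------------------------------------------------------------------

#' DecoderSpec: classifier, regularization grid and validation scheme
#'
#' @slot classifier \code{"svm"} (linear support vector machine) or
#'   \code{"mlr"} (multinomial logistic regression).
#' @slot CGrid ordered regularization constants; \code{Inf} means an
#'   (effectively) unregularized fit.
#' @slot scheme \code{"epochs"}: 5-fold outer cross-validation with balanced
#'   training subsamples and unbalanced test folds (stimulus-class task);
#'   \code{"holdout"}: a single random 80/20 split (direction task).
#' @slot nOuterFolds,innerFolds outer folds (epochs scheme) and inner folds of
#'   the nested C selection.
#' @slot trainFraction training fraction: of the smallest class (balanced
#'   subsampling) or of all samples (holdout).
#' @slot balanceTraining whether training sets are balanced across classes.
#' @slot infC finite stand-in for \code{C = Inf} in the SVM dual (the box
#'   constraint must be finite); MLR uses an exactly unpenalized fit.
#' @export
setClass("DecoderSpec",
  representation(classifier = "character", CGrid = "numeric",
                 scheme = "character", nOuterFolds = "integer",
                 innerFolds = "integer", trainFraction = "numeric",
                 balanceTraining = "logical", infC = "numeric"))

setValidity("DecoderSpec", function(object) {
  msg <- character()
  if (!object@classifier %in% c("svm", "mlr"))
    msg <- c(msg, "classifier must be 'svm' or 'mlr'")
  if (!object@scheme %in% c("epochs", "holdout"))
    msg <- c(msg, "scheme must be 'epochs' or 'holdout'")
  if (length(object@CGrid) == 0 || any(object@CGrid <= 0))
    msg <- c(msg, "CGrid must be non-empty with values > 0 (Inf allowed)")
  if (is.unsorted(object@CGrid))
    msg <- c(msg, "CGrid must be sorted increasingly")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    msg <- c(msg, "trainFraction must be in (0, 1)")
  if (object@nOuterFolds < 2L) msg <- c(msg, "nOuterFolds must be >= 2")
  if (object@innerFolds < 2L) msg <- c(msg, "innerFolds must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct a DecoderSpec
#'
#' @param classifier \code{"svm"} or \code{"mlr"}.
#' @param CGrid regularization grid (default
#'   \code{c(1e-2, 1e-1, 1, 10, 1e2, 1e3, Inf)}).
#' @param scheme \code{"epochs"} or \code{"holdout"}.
#' @param nOuterFolds,innerFolds fold counts.
#' @param trainFraction see class documentation.
#' @param balanceTraining defaults to TRUE for the epochs scheme and FALSE for
#'   holdout (grating trials are balanced by design).
#' @param infC finite realization of \code{C = Inf} for the SVM.
#' @return A \linkS4class{DecoderSpec}.
#' @export
#' @examples
#' decoderSpec("svm")
#' decoderSpec("mlr", scheme = "holdout")
decoderSpec <- function(classifier = c("svm", "mlr"),
                        CGrid = c(1e-2, 1e-1, 1, 10, 1e2, 1e3, Inf),
                        scheme = c("epochs", "holdout"),
                        nOuterFolds = 5L, innerFolds = 4L,
                        trainFraction = 0.8,
                        balanceTraining = NULL, infC = 1e6) {
  classifier <- match.arg(classifier)
  scheme <- match.arg(scheme)
  if (is.null(balanceTraining)) balanceTraining <- scheme == "epochs"
  new("DecoderSpec", classifier = classifier, CGrid = sort(as.numeric(CGrid)),
      scheme = scheme, nOuterFolds = as.integer(nOuterFolds),
      innerFolds = as.integer(innerFolds), trainFraction = trainFraction,
      balanceTraining = isTRUE(balanceTraining), infC = infC)
}

#' DecodingResult: cross-validated decoding performance
#'
#' @slot accuracy overall accuracy, pooled over test folds
#'   (\code{sum(diag(confusion)) / sum(confusion)}).
#' @slot perClassAccuracy named per-class accuracy (rows of the confusion
#'   matrix are true labels).
#' @slot foldAccuracy accuracy of each outer fold (length 1 for holdout).
#' @slot chosenC regularization constant selected by nested CV.
#' @slot confusion confusion matrix (true x predicted).
#' @slot nTrain,nTest per-fold training and test sizes.
#' @slot classifier the classifier used.
#' @export
setClass("DecodingResult",
  representation(accuracy = "numeric", perClassAccuracy = "numeric",
                 foldAccuracy = "numeric", chosenC = "numeric",
                 confusion = "matrix", nTrain = "integer", nTest = "integer",
                 classifier = "character"))

setValidity("DecodingResult", function(object) {
  msg <- character()
  if (object@accuracy < 0 || object@accuracy > 1)
    msg <- c(msg, "accuracy must lie in `[0, 1]`")
  tot <- sum(object@confusion)
  if (tot > 0 &&
      abs(object@accuracy - sum(diag(object@confusion)) / tot) > 1e-12)
    msg <- c(msg, "accuracy must equal trace(confusion)/sum(confusion)")
  pc <- object@perClassAccuracy[is.finite(object@perClassAccuracy)]
  if (length(pc) && (any(pc < 0) || any(pc > 1)))
    msg <- c(msg, "per-class accuracies must lie in `[0, 1]`")
  if (length(msg)) msg else TRUE
})

#' AccuracyCurve: accuracy as a function of population size
#'
#' Holds mean decoding accuracy at neuron-subsample sizes
#' \eqn{1, 2, 4, \ldots} (plus the full population) and, after
#' \code{\link{fitAccuracyCurve}}, the parameters of the constrained
#' generalized logistic
#' \deqn{\mathrm{accuracy}(n) = \frac{1 - c}{(1 + e^{-an})^b} + c,}
#' with \eqn{a \ge 0}, \eqn{b \in [0,1]}, \eqn{c \ge 0}.
#'
#' @slot sizes subsample sizes (strictly increasing).
#' @slot accuracies list of per-size resample accuracies.
#' @slot meanAccuracy per-size mean accuracy.
#' @slot nResamples number of neuron resamples per size.
#' @slot fit list with elements \code{a}, \code{b}, \code{c},
#'   \code{residual} (SSE), \code{converged}; empty before fitting.
#' @slot task label of the decoded variable.
#' @export
setClass("AccuracyCurve",
  representation(sizes = "integer", accuracies = "list",
                 meanAccuracy = "numeric", nResamples = "integer",
                 fit = "list", task = "character"))

setValidity("AccuracyCurve", function(object) {
  msg <- character()
  if (length(object@sizes) > 1L && any(diff(object@sizes) <= 0))
    msg <- c(msg, "sizes must be strictly increasing")
  acc <- unlist(object@accuracies, use.names = FALSE)
  if (length(acc) && (any(acc < 0) || any(acc > 1)))
    msg <- c(msg, "accuracies must lie in `[0, 1]`")
  if (length(object@fit)) {
    f <- object@fit
    if (f$a < 0 || f$b < 0 || f$b > 1 || f$c < 0)
      msg <- c(msg, "fitted parameters must satisfy a >= 0, b in [0,1], c >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' SynergyResult: joint versus correlation-blind decoding
#'
#' @slot joint per-replicate accuracy of the decoder trained on intact data.
#' @slot independent per-replicate accuracy of the correlation-blind decoder
#'   (trained on within-class trial-shuffled data, tested on intact data;
#'   averaged over shuffle repeats).
#' @slot delta mean(joint) - mean(independent).
#' @slot pairedTest list with \code{t}, \code{p}, \code{df} from the paired t
#'   test across replicates (elements NA if the test is undefined).
#' @export
setClass("SynergyResult",
  representation(joint = "numeric", independent = "numeric",
                 delta = "numeric", pairedTest = "list"))

setValidity("SynergyResult", function(object) {
  ok <- function(x) all(x >= 0 & x <= 1)
  if (!ok(object@joint) || !ok(object@independent))
    "accuracies must lie in `[0, 1]`" else TRUE
})
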