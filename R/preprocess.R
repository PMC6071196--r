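#' @include AllClasses.R
NULL

#' Compute \eqn{\Delta F/F} with a sliding 1-s baseline
#'
#' For every frame \eqn{t}, \eqn{\Delta F/F = (F(t) - F_0(t)) / F_0(t)} where
#' \eqn{F_0(t)} is the mean fluorescence over the frames of the preceding
#' \code{baselineWindowS} seconds (frame \eqn{t} excluded). Frames closer to
#' the recording onset than one full window use all available preceding
#' frames; the very first frame has no baseline and is returned as \code{NA}.
#'
#' @param rec a \linkS4class{FluorescenceRecording}.
#' @param baselineWindowS baseline window length in seconds (> 0).
#' @return Numeric matrix of \eqn{\Delta F/F}, same dimensions and dimnames as
#'   the fluorescence assay (first column \code{NA}).
#' @export
#' @examples
#' rec <- fluorescenceRecording(matrix(100, 1, 60), (0:59) / 30, "n1", "A")
#' range(computeDFF(rec)[, -1])
computeDFF <- function(rec, baselineWindowS = 1.0) {
  stopifnot(is(rec, "FluorescenceRecording"), baselineWindowS > 0)
  f <- fluorescence(rec)
  ts <- timestamps(rec)
  nT <- length(ts)
  if (nT >= 2L) {
    dt <- stats::median(diff(ts))
    if (baselineWindowS < 2 * dt)
      stop("baseline window must span at least 2 frames")
  }
  ## first frame of each window: smallest j with ts[j] >= ts[t] - window
  lo <- findInterval(ts - baselineWindowS, ts, left.open = TRUE) + 1L
  hi <- seq_len(nT) - 1L
  cs <- cbind(0, t(apply(f, 1L, cumsum)))
  cnt <- hi - lo + 1L
  ok <- cnt >= 1L
  f0 <- matrix(NA_real_, nrow(f), nT, dimnames = dimnames(f))
  f0[, ok] <- (cs[, hi[ok] + 1L, drop = FALSE] -
                 cs[, lo[ok], drop = FALSE]) / rep(cnt[ok], each = nrow(f))
  if (any(f0[, ok] <= 0))
    stop("baseline F0 is zero or negative; raw fluorescence must be positive")
  (f - f0) / f0
}

## frames whose midpoints fall in [a, b); mids precomputed by caller
.framesInWindow <- function(mids, a, b) {
  i0 <- findInterval(a, mids, left.open = TRUE) + 1L
  i1 <- findInterval(b - 1e-9, mids)
  if (i1 < i0) integer() else i0:i1
}

#' Segment stimulus-class epochs into fixed-length interval samples
#'
#' Each epoch is tiled from its start with \code{intervalS}-second intervals;
#' a trailing interval shorter than \code{intervalS} is discarded. Every
#' complete interval becomes one sample: the per-neuron mean \eqn{\Delta F/F}
#' over the interval, labeled with the epoch's stimulus class. Frames are
#' assigned to intervals by the membership of their temporal midpoints.
#'
#' @param dff \eqn{\Delta F/F} matrix from \code{\link{computeDFF}}
#'   (neurons x frames).
#' @param timestamps frame times in seconds.
#' @param epochs data.frame with columns \code{start_s}, \code{stop_s},
#'   \code{class}; epochs must not overlap.
#' @param intervalS interval length in seconds (default 10).
#' @param sessionId optional session label stored per sample.
#' @return An unnormalized \linkS4class{FeatureDataset}.
#' @export
segmentClassEpochs <- function(dff, timestamps, epochs, intervalS = 10,
                               sessionId = NA_character_) {
  stopifnot(intervalS > 0,
            all(c("start_s", "stop_s", "class") %in% names(epochs)))
  ep <- epochs[order(epochs$start_s), , drop = FALSE]
  if (nrow(ep) > 1L && any(ep$start_s[-1] < ep$stop_s[-nrow(ep)] - 1e-9))
    stop("epochs must be non-overlapping")
  dt <- stats::median(diff(timestamps))
  mids <- timestamps + dt / 2
  feats <- list(); labs <- character(); win <- NULL
  for (k in seq_len(nrow(ep))) {
    nInt <- floor((ep$stop_s[k] - ep$start_s[k]) / intervalS + 1e-9)
    for (j in seq_len(nInt)) {
      a <- ep$start_s[k] + (j - 1) * intervalS
      idx <- .framesInWindow(mids, a, a + intervalS)
      if (!length(idx)) next
      feats[[length(feats) + 1L]] <-
        rowMeans(dff[, idx, drop = FALSE], na.rm = TRUE)
      labs <- c(labs, ep$class[k])
      win <- rbind(win, c(a, a + intervalS))
    }
  }
  if (!length(feats)) stop("no complete intervals; epochs too short")
  featureDataset(do.call(cbind, feats), labs, neuronIds = rownames(dff),
                 windows = win,
                 colData = list(session = rep(sessionId, length(labs))))
}

#' Segment drifting-grating trials into direction-labeled samples
#'
#' One sample per trial: the per-neuron mean \eqn{\Delta F/F} over the 2-s
#' grating-on window \code{[onset_s, onset_s + duration_s)}; the following
#' gray second is discarded. Samples are labeled with the grating direction;
#' the temporal frequency is kept as metadata.
#'
#' @param dff \eqn{\Delta F/F} matrix (neurons x frames).
#' @param timestamps frame times in seconds.
#' @param trials data.frame with columns \code{onset_s}, \code{duration_s},
#'   \code{direction_deg}, \code{temporal_freq_hz}.
#' @param sessionId optional session label stored per sample.
#' @return An unnormalized \linkS4class{FeatureDataset} with
#'   \code{direction_deg} and \code{temporal_freq_hz} in \code{colData()}.
#' @export
segmentGratingTrials <- function(dff, timestamps, trials,
                                 sessionId = NA_character_) {
  need <- c("onset_s", "duration_s", "direction_deg", "temporal_freq_hz")
  stopifnot(all(need %in% names(trials)))
  dt <- stats::median(diff(timestamps))
  if (any(trials$onset_s + trials$duration_s >
            timestamps[length(timestamps)] + dt + 1e-9))
    stop("trial extends past the end of the recording")
  mids <- timestamps + dt / 2
  feats <- vapply(seq_len(nrow(trials)), function(k) {
    idx <- .framesInWindow(mids, trials$onset_s[k],
                           trials$onset_s[k] + trials$duration_s[k])
    if (!length(idx)) stop("trial ", k, " covers no frames")
    rowMeans(dff[, idx, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(dff)))
  featureDataset(matrix(feats, nrow = nrow(dff)),
                 labels = as.character(trials$direction_deg),
                 neuronIds = rownames(dff),
                 windows = cbind(trials$onset_s,
                                 trials$onset_s + trials$duration_s),
                 colData = list(direction_deg = trials$direction_deg,
                                temporal_freq_hz = trials$temporal_freq_hz,
                                session = rep(sessionId, nrow(trials))))
}

#' Restrict feature datasets to their common neurons
#'
#' Restricts every dataset to the sorted intersection of neuron identifiers,
#' column-aligning the feature matrices, mirroring the use of neurons imaged
#' in all three sessions.
#'
#' @param datasets list of \linkS4class{FeatureDataset}s.
#' @return List of datasets, each restricted to the shared neurons.
#' @export
intersectNeurons <- function(datasets) {
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, is, logical(1), "FeatureDataset")))
  common <- Reduce(intersect, lapply(datasets, rownames))
  if (!length(common)) stop("no neurons are common to all datasets")
  common <- sort(common)
  lapply(datasets, function(d) d[common, ])
}

#' Concatenate feature datasets sample-wise
#'
#' Binds the samples of several datasets (e.g. the three sessions) after
#' restricting them to their common neurons.
#'
#' @param datasets list of \linkS4class{FeatureDataset}s.
#' @return A single \linkS4class{FeatureDataset}.
#' @export
combineFeatureDatasets <- function(datasets) {
  datasets <- intersectNeurons(datasets)
  cols <- Reduce(intersect, lapply(datasets, function(d) colnames(colData(d))))
  datasets <- lapply(datasets, function(d) {
    colData(d) <- colData(d)[, cols, drop = FALSE]
    d
  })
  out <- do.call(cbind, datasets)
  metadata(out) <- list(zscored = all(vapply(datasets, isZscored, logical(1))))
  out
}

#' z-score features per neuron
#'
#' Centers and scales every neuron's feature values over all samples of the
#' dataset, using the population-SD convention (divide by \eqn{n}). Applied
#' once over the whole dataset, before any train/test split. Neurons with
#' zero variance are mapped to all-zero rows with a warning.
#'
#' @param ds a \linkS4class{FeatureDataset}.
#' @return The z-scored \linkS4class{FeatureDataset}
#'   (\code{isZscored(ds)} is \code{TRUE}).
#' @export
zscoreFeatures <- function(ds) {
  stopifnot(is(ds, "FeatureDataset"))
  x <- featureMatrix(ds)
  mu <- rowMeans(x)
  sdp <- sqrt(rowMeans((x - mu)^2))
  bad <- sdp <= 0 | !is.finite(sdp)
  if (any(bad)) {
    warning(sum(bad), " neuron(s) with zero variance mapped to all-zero rows")
    sdp[bad] <- 1
  }
  z <- (x - mu) / sdp
  z[bad, ] <- 0
  assay(ds, "features") <- z
  metadata(ds)$zscored <- TRUE
  ds
}
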