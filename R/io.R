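#' @include AllClasses.R
NULL

#' Plain-text readers and writers
#'
#' All on-disk formats are plain text: fluorescence recordings as a wide CSV
#' (first column \code{timestamp}, one column per neuron), epoch and trial
#' tables as CSV with the canonical headers, feature datasets as a features
#' CSV (neurons x samples, neuron ids in the first column) plus a sample
#' manifest CSV, and results as JSON.
#'
#' @param rec,ds,epochs,trials,x object to write.
#' @param path,prefix file path, or path prefix for the two feature-dataset
#'   files (\code{<prefix>_features.csv}, \code{<prefix>_samples.csv}).
#' @name popdecode-io
NULL

#' @rdname popdecode-io
#' @export
writeRecordingCsv <- function(rec, path) {
  stopifnot(is(rec, "FluorescenceRecording"))
  df <- data.frame(timestamp = timestamps(rec),
                   t(fluorescence(rec)), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname popdecode-io
#' @param sessionId session label for the re-read recording.
#' @export
readRecordingCsv <- function(path, sessionId = NA_character_) {
  df <- read.csv(path, check.names = FALSE)
  fluorescenceRecording(t(as.matrix(df[, -1, drop = FALSE])),
                        df$timestamp, colnames(df)[-1], sessionId)
}

#' @rdname popdecode-io
#' @export
writeEpochTable <- function(epochs, path) {
  write.csv(epochs[, c("start_s", "stop_s", "class")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname popdecode-io
#' @export
readEpochTable <- function(path) read.csv(path)

#' @rdname popdecode-io
#' @export
writeTrialTable <- function(trials, path) {
  write.csv(trials[, c("onset_s", "duration_s", "direction_deg",
                       "temporal_freq_hz")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname popdecode-io
#' @export
readTrialTable <- function(path) read.csv(path)

#' @rdname popdecode-io
#' @export
writeFeatureDataset <- function(ds, prefix) {
  stopifnot(is(ds, "FeatureDataset"))
  feat <- data.frame(neuron_id = rownames(ds), featureMatrix(ds),
                     check.names = FALSE)
  write.csv(feat, paste0(prefix, "_features.csv"), row.names = FALSE)
  write.csv(as.data.frame(colData(ds)), paste0(prefix, "_samples.csv"),
            row.names = FALSE)
  invisible(prefix)
}

#' @rdname popdecode-io
#' @export
readFeatureDataset <- function(prefix) {
  feat <- read.csv(paste0(prefix, "_features.csv"), check.names = FALSE)
  cd <- read.csv(paste0(prefix, "_samples.csv"))
  x <- as.matrix(feat[, -1, drop = FALSE])
  dimnames(x) <- NULL
  featureDataset(x, labels = cd$label, neuronIds = feat$neuron_id,
                 colData = cd[, setdiff(names(cd), "label"), drop = FALSE])
}

#' @rdname popdecode-io
#' @export
writeResultJson <- function(x, path) {
  if (is(x, "DecodingResult"))
    x <- list(accuracy = accuracy(x),
              per_class_accuracy = as.list(perClassAccuracy(x)),
              chosen_C = chosenC(x), fold_accuracy = x@foldAccuracy,
              confusion = confusionMatrix(x),
              n_train = x@nTrain, n_test = x@nTest,
              classifier = x@classifier)
  else if (is(x, "AccuracyCurve"))
    x <- list(sizes = curveSizes(x), accuracies = x@accuracies,
              mean_accuracy = meanAccuracy(x), fit = fitParams(x),
              task = x@task)
  else if (is(x, "SynergyResult"))
    x <- list(joint = x@joint, independent = x@independent,
              delta = synergyDelta(x), paired_test = x@pairedTest)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}
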