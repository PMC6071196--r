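#' @include AllGenerics.R
NULL

## FluorescenceRecording ------------------------------------------------------

#' @rdname accessors
#' @aliases fluorescence,FluorescenceRecording-method
#' @export
setMethod("fluorescence", "FluorescenceRecording",
          function(object, ...) assay(object, "fluorescence"))

#' @rdname accessors
#' @export
setMethod("timestamps", "FluorescenceRecording",
          function(object, ...) colData(object)$timestamp)

#' @rdname accessors
#' @export
setMethod("neuronIds", "FluorescenceRecording",
          function(object, ...) rownames(object))

#' @rdname accessors
#' @export
setMethod("sessionId", "FluorescenceRecording",
          function(object, ...) metadata(object)$session_id)

setMethod("show", "FluorescenceRecording", function(object) {
  ts <- timestamps(object)
  cat(sprintf(
    "FluorescenceRecording, session %s: %d neurons x %d frames (%.1f s)\n",
    sessionId(object), nrow(object), ncol(object),
    if (length(ts)) diff(range(ts)) else 0))
})

## FeatureDataset -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureDataset",
          function(object, ...) assay(object, "features"))

#' @rdname accessors
#' @export
setMethod("sampleLabels", "FeatureDataset",
          function(object, ...) colData(object)$label)

#' @rdname accessors
#' @export
setMethod("sampleWindows", "FeatureDataset", function(object, ...) {
  cd <- colData(object)
  if (!all(c("window_start", "window_stop") %in% colnames(cd)))
    return(NULL)
  cbind(start_s = cd$window_start, stop_s = cd$window_stop)
})

#' @rdname accessors
#' @export
setMethod("neuronIds", "FeatureDataset",
          function(object, ...) rownames(object))

#' @rdname accessors
#' @export
setMethod("isZscored", "FeatureDataset",
          function(object, ...) isTRUE(metadata(object)$zscored))

setMethod("show", "FeatureDataset", function(object) {
  labs <- table(sampleLabels(object))
  cat(sprintf("FeatureDataset: %d neurons x %d samples (%s)\n",
              nrow(object), ncol(object),
              if (isZscored(object)) "z-scored" else "unnormalized"))
  cat("  labels:",
      paste(sprintf("%s=%d", names(labs), as.integer(labs)), collapse = ", "),
      "\n")
})

## DecodingResult -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("accuracy", "DecodingResult", function(object, ...) object@accuracy)

#' @rdname accessors
#' @export
setMethod("perClassAccuracy", "DecodingResult",
          function(object, ...) object@perClassAccuracy)

#' @rdname accessors
#' @export
setMethod("confusionMatrix", "DecodingResult",
          function(object, ...) object@confusion)

#' @rdname accessors
#' @export
setMethod("chosenC", "DecodingResult", function(object, ...) object@chosenC)

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult (%s): accuracy %.3f over %d classes, C = %s\n",
              object@classifier, object@accuracy, nrow(object@confusion),
              format(object@chosenC)))
})

## AccuracyCurve --------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("curveSizes", "AccuracyCurve", function(object, ...) object@sizes)

#' @rdname accessors
#' @export
setMethod("meanAccuracy", "AccuracyCurve",
          function(object, ...) object@meanAccuracy)

#' @rdname accessors
#' @export
setMethod("fitParams", "AccuracyCurve", function(object, ...) object@fit)

setMethod("show", "AccuracyCurve", function(object) {
  cat(sprintf("AccuracyCurve (%s): sizes %s\n", object@task,
              paste(object@sizes, collapse = ", ")))
  cat("  mean accuracy:",
      paste(sprintf("%.3f", object@meanAccuracy), collapse = ", "), "\n")
  if (length(object@fit))
    cat(sprintf("  fit: a = %.4g, b = %.4g, c = %.4g (SSE %.3g)\n",
                object@fit$a, object@fit$b, object@fit$c, object@fit$residual))
  else cat("  (unfitted)\n")
})

## SynergyResult --------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("accuracy", "SynergyResult", function(object, ...)
  c(joint = mean(object@joint), independent = mean(object@independent)))

#' @rdname accessors
#' @export
setMethod("synergyDelta", "SynergyResult", function(object, ...) object@delta)

setMethod("show", "SynergyResult", function(object) {
  cat(sprintf(
    "SynergyResult: joint %.3f vs correlation-blind %.3f (delta %+.3f)\n",
    mean(object@joint), mean(object@independent), object@delta))
  pt <- object@pairedTest
  if (!is.null(pt$t) && is.finite(pt$t))
    cat(sprintf("  paired t(%d) = %.3f, p = %.3g\n", pt$df, pt$t, pt$p))
})
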