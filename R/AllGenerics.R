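#' @include AllClasses.R
NULL

#' Accessors for popdecode objects
#'
#' Small camelCase accessor generics for the S4 result and data classes.
#'
#' @param object an object of the documented class.
#' @param ... further arguments for methods.
#' @return The corresponding slot or derived value.
#' @name accessors
NULL

#' Re-exported generics
#'
#' The \code{decode} generic is re-exported from \pkg{S4Vectors}; this package
#' registers the \linkS4class{FeatureDataset} decoding method on it.
#'
#' @name decode
#' @importFrom S4Vectors decode
#' @export decode
NULL

#' @rdname accessors
#' @export
setGeneric("fluorescence", function(object, ...) standardGeneric("fluorescence"))

#' @rdname accessors
#' @export
setGeneric("timestamps", function(object, ...) standardGeneric("timestamps"))

#' @rdname accessors
#' @export
setGeneric("neuronIds", function(object, ...) standardGeneric("neuronIds"))

#' @rdname accessors
#' @export
setGeneric("sessionId", function(object, ...) standardGeneric("sessionId"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(object, ...) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(object, ...) standardGeneric("sampleLabels"))

#' @rdname accessors
#' @export
setGeneric("sampleWindows", function(object, ...) standardGeneric("sampleWindows"))

#' @rdname accessors
#' @export
setGeneric("isZscored", function(object, ...) standardGeneric("isZscored"))

#' @rdname accessors
#' @export
setGeneric("accuracy", function(object, ...) standardGeneric("accuracy"))

#' @rdname accessors
#' @export
setGeneric("perClassAccuracy", function(object, ...)
  standardGeneric("perClassAccuracy"))

#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(object, ...)
  standardGeneric("confusionMatrix"))

#' @rdname accessors
#' @export
setGeneric("chosenC", function(object, ...) standardGeneric("chosenC"))

#' @rdname accessors
#' @export
setGeneric("curveSizes", function(object, ...) standardGeneric("curveSizes"))

#' @rdname accessors
#' @export
setGeneric("meanAccuracy", function(object, ...) standardGeneric("meanAccuracy"))

#' @rdname accessors
#' @export
setGeneric("fitParams", function(object, ...) standardGeneric("fitParams"))

#' @rdname accessors
#' @export
setGeneric("synergyDelta", function(object, ...) standardGeneric("synergyDelta"))

#' Evaluate a fitted accuracy curve at population size n
#'
#' @param object a fitted \linkS4class{AccuracyCurve} (see
#'   \code{\link{fitAccuracyCurve}}).
#' @param n population size(s) at which to evaluate the generalized logistic.
#' @return Numeric vector of accuracies.
#' @export
setGeneric("extrapolateAccuracy", function(object, n)
  standardGeneric("extrapolateAccuracy"))
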