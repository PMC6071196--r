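#' @include decode.R
NULL

#' The constrained generalized logistic accuracy model
#'
#' Evaluates \deqn{\mathrm{accuracy}(n) = \frac{1 - c}{(1 + e^{-an})^b} + c}
#' with \eqn{a \ge 0}, \eqn{b \in [0, 1]}, \eqn{c \ge 0}. The curve rises from
#' \eqn{(1 - c)/2^b + c} at \eqn{n = 0} toward 1 as \eqn{n \to \infty}; the
#' \eqn{c} parameter accommodates the chance-level floor at small population
#' sizes.
#'
#' @param n population size(s).
#' @param a,b,c curve parameters.
#' @return Accuracy value(s).
#' @export
#' @examples
#' generalizedLogistic(0, a = 1, b = 1, c = 1/6)  # (1 - 1/6)/2 + 1/6
generalizedLogistic <- function(n, a, b, c) {
  (1 - c) / (1 + exp(-a * n))^b + c
}

#' Decoding accuracy versus population size
#'
#' For each subsample size \eqn{n \in \{1, 2, 4, \ldots\}} (plus the full
#' population when it is not a power of two), draws \code{nResamples} random
#' neuron subsets without replacement, runs the full decoding procedure on
#' each, and records the mean accuracy per size. The full-population size is
#' evaluated once (there is only one such subset).
#'
#' @param ds a \linkS4class{FeatureDataset}.
#' @param spec a \linkS4class{DecoderSpec}.
#' @param nResamples neuron resamples per size (default 10).
#' @param seed integer seed.
#' @return An unfitted \linkS4class{AccuracyCurve}.
#' @export
subsampleCurve <- function(ds, spec = decoderSpec(), nResamples = 10,
                           seed = 1) {
  stopifnot(is(ds, "FeatureDataset"), nrow(ds) >= 1L)
  n <- nrow(ds)
  sizes <- 2^(0:floor(log2(n)))
  if (sizes[length(sizes)] < n) sizes <- c(sizes, n)
  sizes <- as.integer(sizes)
  res <- withr::with_seed(as.integer(seed), {
    lapply(sizes, function(s) {
      reps <- if (s == n) 1L else as.integer(nResamples)
      vapply(seq_len(reps), function(r) {
        sub <- sort(sample.int(n, s))
        dseed <- sample.int(2^30, 1L)
        accuracy(decode(ds[sub, ], spec, seed = dseed))
      }, numeric(1))
    })
  })
  new("AccuracyCurve", sizes = sizes, accuracies = res,
      meanAccuracy = vapply(res, mean, numeric(1)),
      nResamples = as.integer(nResamples), fit = list(),
      task = spec@scheme)
}

#' Build an AccuracyCurve from precomputed accuracies
#'
#' @param sizes population sizes.
#' @param accuracies numeric vector of per-size accuracies, or a list of
#'   per-size resample accuracy vectors.
#' @param task label of the decoded variable.
#' @return An unfitted \linkS4class{AccuracyCurve}.
#' @export
accuracyCurve <- function(sizes, accuracies, task = "custom") {
  if (is.numeric(accuracies)) accuracies <- as.list(accuracies)
  new("AccuracyCurve", sizes = as.integer(sizes), accuracies = accuracies,
      meanAccuracy = vapply(accuracies, mean, numeric(1)),
      nResamples = max(lengths(accuracies)), fit = list(), task = task)
}

#' Fit the generalized logistic to an accuracy curve
#'
#' Constrained nonlinear least squares on the per-size mean accuracies:
#' bounded L-BFGS-B on the sum of squared errors with bounds \eqn{a \ge 0},
#' \eqn{b \in [0, 1]}, \eqn{0 \le c \le 1}, from three starting points to
#' avoid local minima. Non-convergence of every start is an error carrying
#' the optimizer diagnostics.
#'
#' @param curve an \linkS4class{AccuracyCurve} with at least 3 size points,
#'   or a list/data.frame-like pair via \code{sizes} and \code{accuracy}.
#' @param startC starting value for the chance-floor parameter \code{c}
#'   (defaults to the smallest observed mean accuracy).
#' @return The curve with its \code{fit} slot populated
#'   (\code{a}, \code{b}, \code{c}, \code{residual} = SSE, \code{converged}).
#' @export
#' @examples
#' acc <- generalizedLogistic(2^(0:7), 0.05, 0.8, 1/6)
#' fitParams(fitAccuracyCurve(accuracyCurve(2^(0:7), acc)))[c("a", "b", "c")]
fitAccuracyCurve <- function(curve, startC = NULL) {
  stopifnot(is(curve, "AccuracyCurve"))
  nPts <- length(curve@sizes)
  if (nPts < 3L) stop("need at least 3 (size, accuracy) points")
  nn <- as.numeric(curve@sizes)
  yy <- curve@meanAccuracy
  sse <- function(p) {
    r <- yy - generalizedLogistic(nn, p[1], p[2], p[3])
    sum(r * r)
  }
  sseGrad <- function(p) {
    S <- 1 + exp(-p[1] * nn)
    Smb <- S^(-p[2])
    f <- (1 - p[3]) * Smb + p[3]
    r <- yy - f
    dfa <- (1 - p[3]) * p[2] * nn * exp(-p[1] * nn) * Smb / S
    dfb <- -(1 - p[3]) * Smb * log(S)
    dfc <- 1 - Smb
    -2 * c(sum(r * dfa), sum(r * dfb), sum(r * dfc))
  }
  c0 <- if (is.null(startC)) max(min(yy), 1e-3) else startC
  starts <- list(c(0.1, 0.5, min(c0, 0.999)),
                 c(0.01, 0.9, min(c0, 0.999)),
                 c(1, 0.2, min(c0 / 2, 0.999)))
  bounded <- function(par) tryCatch(
    stats::optim(par, sse, gr = sseGrad, method = "L-BFGS-B",
                 lower = c(0, 0, 0), upper = c(Inf, 1, 1),
                 control = list(maxit = 1000, factr = 1e3)),
    error = function(e) list(convergence = 99L,
                             message = conditionMessage(e),
                             value = Inf, par = par))
  best <- NULL
  msgs <- character()
  for (s in starts) {
    o <- bounded(s)
    ## a line-search abort (code 52) still returns a usable point; restarting
    ## from it typically reaches the optimum
    for (r in 1:2)
      if (o$convergence != 0L && is.finite(o$value)) {
        o2 <- bounded(o$par)
        if (o2$value <= o$value) o <- o2 else break
      }
    msgs <- c(msgs, sprintf("start (%s): code %d %s",
                            paste(signif(s, 3), collapse = ", "),
                            o$convergence,
                            if (is.null(o$message)) "" else o$message))
    if (is.finite(o$value) && (is.null(best) || o$value < best$value))
      best <- o
  }
  if (is.null(best))
    stop("generalized-logistic fit did not converge:\n",
         paste(msgs, collapse = "\n"))
  curve@fit <- list(a = best$par[1], b = best$par[2], c = best$par[3],
                    residual = best$value,
                    converged = best$convergence == 0L)
  validObject(curve)
  curve
}

#' @rdname extrapolateAccuracy
#' @export
setMethod("extrapolateAccuracy", "AccuracyCurve", function(object, n) {
  if (!length(object@fit))
    stop("curve is unfitted; run fitAccuracyCurve() first")
  generalizedLogistic(n, object@fit$a, object@fit$b, object@fit$c)
})
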