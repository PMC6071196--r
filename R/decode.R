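#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## classifier backends
## ---------------------------------------------------------------------------

## one-vs-rest linear SVM via the package's dual coordinate-descent solver;
## returns (p+1) x K weight matrix (last row = bias)
.fitSvmOvr <- function(x, y, C) {
  lev <- levels(y)
  W <- vapply(lev, function(l) {
    yy <- ifelse(y == l, 1, -1)
    .linsvmDcd(x, yy, C)
  }, numeric(ncol(x) + 1L))
  list(type = "svm", W = W, levels = lev)
}

.fitMlr <- function(x, y, C) {
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  df <- data.frame(.y = y, x, check.names = FALSE)
  decay <- if (is.infinite(C)) 0 else 1 / (2 * C)
  fit <- nnet::multinom(.y ~ ., data = df, decay = decay, trace = FALSE,
                        maxit = 200, MaxNWts = 1e5)
  list(type = "mlr", fit = fit, levels = levels(y))
}

.fitClassifier <- function(x, y, spec, C) {
  if (spec@classifier == "svm")
    .fitSvmOvr(x, y, min(C, spec@infC))
  else
    .fitMlr(x, y, C)
}

.predictClassifier <- function(model, x) {
  if (model$type == "svm") {
    scores <- cbind(x, 1) %*% model$W
    factor(model$levels[max.col(scores, ties.method = "first")],
           levels = model$levels)
  } else {
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    pred <- predict(model$fit, newdata = as.data.frame(x), type = "class")
    factor(as.character(pred), levels = model$levels)
  }
}

## ---------------------------------------------------------------------------
## splits
## ---------------------------------------------------------------------------

## balanced subsample of `pool`: floor(frac * smallest class) per class
## (assumes RNG already seeded by the caller)
.balancedIdx <- function(y, pool, frac) {
  tab <- table(droplevels(y[pool]))
  k <- floor(frac * min(tab))
  if (k < 1)
    stop("balanced training subsample is empty (smallest class has ",
         min(tab), " samples)")
  sort(unlist(lapply(names(tab), function(l) {
    idx <- pool[y[pool] == l]
    idx[sample.int(length(idx), k)]
  }), use.names = FALSE))
}

## stratified folds that keep each class's samples in their original
## (temporal) order and cut them into consecutive chunks -- the fold
## construction of scikit-learn's StratifiedKFold without shuffling, which the
## decoding scheme mirrors. Samples adjacent in time therefore stay in the
## same fold, so fold-wise testing is not confounded by the short-range
## dependence between neighboring intervals of one epoch.
.stratifiedFolds <- function(y, k) {
  out <- integer(length(y))
  for (l in levels(y)) {
    idx <- which(y == l)
    cuts <- round(seq(0, length(idx), length.out = k + 1))
    out[idx] <- rep(seq_len(k), diff(cuts))
  }
  out
}

## permute training-set values within class, per feature (column)
.shuffleTrainX <- function(x, y, seed) {
  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    for (l in levels(y)) {
      idx <- which(y == l)
      if (length(idx) > 1L)
        x[idx, ] <- apply(x[idx, , drop = FALSE], 2L,
                          function(v) v[sample.int(length(v))])
    }
  })
  x
}

#' Balanced training / unbalanced test split
#'
#' Draws, without replacement, an equal number of samples from each class —
#' \code{floor(trainFraction * size of the smallest class)} per class — as the
#' training set; all remaining samples form the (unbalanced) test set.
#'
#' @param ds a \linkS4class{FeatureDataset}.
#' @param seed integer seed.
#' @param trainFraction fraction of the smallest class used per class.
#' @return List with sorted integer vectors \code{train} and \code{test}.
#' @export
#' @examples
#' fd <- featureDataset(matrix(rnorm(40), 2), rep(c("a", "b"), c(12, 8)))
#' balancedTrainSplit(fd, seed = 1)
balancedTrainSplit <- function(ds, seed = 1, trainFraction = 0.8) {
  y <- factor(sampleLabels(ds))
  if (any(table(y) < 2)) stop("every class needs at least 2 samples")
  tr <- withr::with_seed(as.integer(seed),
                         .balancedIdx(y, seq_along(y), trainFraction))
  list(train = sort(tr), test = sort(setdiff(seq_along(y), tr)))
}

#' Uniform random train/test split
#'
#' @param ds a \linkS4class{FeatureDataset}.
#' @param trainFraction fraction of samples assigned to training.
#' @param seed integer seed.
#' @return List with sorted integer vectors \code{train} and \code{test}.
#' @export
randomSplit <- function(ds, trainFraction = 0.8, seed = 1) {
  n <- ncol(ds)
  stopifnot(n >= 5)
  tr <- withr::with_seed(as.integer(seed),
                         sample.int(n, floor(trainFraction * n)))
  list(train = sort(tr), test = sort(setdiff(seq_len(n), tr)))
}

## ---------------------------------------------------------------------------
## nested C selection
## ---------------------------------------------------------------------------

## inner cross-validation over the C grid; ties go to the smaller C
## (grid is sorted; which.max returns the first maximum)
.selectC <- function(x, y, spec) {
  grid <- spec@CGrid
  if (length(grid) == 1L) return(grid)
  innerK <- min(spec@innerFolds, min(table(y)))
  if (innerK < 2L) return(grid[1L])
  folds <- .stratifiedFolds(y, innerK)
  acc <- vapply(grid, function(C) {
    mean(vapply(seq_len(innerK), function(f) {
      tr <- folds != f
      fit <- .fitClassifier(x[tr, , drop = FALSE], droplevels(y[tr]), spec, C)
      pred <- .predictClassifier(fit, x[!tr, , drop = FALSE])
      mean(pred == y[!tr])
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(acc)]
}

#' Select the regularization constant by nested cross-validation
#'
#' Runs the inner cross-validation of the nested scheme on a training set and
#' returns the grid value with the highest validation accuracy; ties are
#' broken toward the smaller C (stronger regularization).
#'
#' @param ds a \linkS4class{FeatureDataset} (the training set).
#' @param spec a \linkS4class{DecoderSpec}.
#' @param seed integer seed for the inner folds.
#' @return The chosen C (may be \code{Inf}).
#' @export
selectRegularization <- function(ds, spec = decoderSpec(), seed = 1) {
  x <- t(featureMatrix(ds))
  y <- droplevels(factor(sampleLabels(ds)))
  withr::with_seed(as.integer(seed), .selectC(x, y, spec))
}

## ---------------------------------------------------------------------------
## decode
## ---------------------------------------------------------------------------

#' Decode stimulus labels from population feature vectors
#'
#' Trains and evaluates the linear decoder of \code{spec}.
#' \describe{
#'   \item{epochs scheme}{5-fold outer cross-validation: each outer fold's
#'     training portion is reduced to a balanced subsample
#'     (\code{floor(0.8 x smallest class)} per class); the test fold is kept
#'     unbalanced. The regularization constant is selected once, by inner
#'     cross-validation within the first outer training set, and reused.}
#'   \item{holdout scheme}{a single random 80/20 split (direction task), with
#'     C selected by inner cross-validation within the training set.}
#' }
#' Results are deterministic given \code{(ds, spec, seed)}.
#'
#' @param x a \linkS4class{FeatureDataset} (normally z-scored).
#' @param spec a \linkS4class{DecoderSpec}.
#' @param seed integer seed.
#' @param blind if \code{TRUE}, training data (only) are within-class
#'   trial-shuffled before fitting — the correlation-blind decoder. Test data
#'   stay intact.
#' @param blindSeed seed of the shuffle (isolated from the split RNG so that
#'   blind and joint runs with the same \code{seed} share identical splits).
#' @return A \linkS4class{DecodingResult}.
#' @aliases decode
#' @export
#' @examples
#' m <- tunedPopulationModel(6, classSeparation = 0.4)
#' fd <- zscoreFeatures(simulateTrialResponses(m, gratingPlan(3), seed = 2))
#' decode(fd, decoderSpec("svm", scheme = "holdout"), seed = 1)
setMethod("decode", "FeatureDataset",
          function(x, spec = decoderSpec(), seed = 1, blind = FALSE,
                   blindSeed = seed + 101) {
  ds <- x
  stopifnot(is(spec, "DecoderSpec"))
  x <- t(featureMatrix(ds))
  y <- droplevels(factor(sampleLabels(ds)))
  if (nlevels(y) < 2L) stop("decoding needs at least 2 classes")
  lev <- levels(y)
  conf <- matrix(0, nlevels(y), nlevels(y), dimnames = list(lev, lev))
  foldAcc <- numeric(); nTrain <- integer(); nTest <- integer()
  chosen <- NA_real_

  withr::with_seed(as.integer(seed), {
    if (spec@scheme == "epochs") {
      folds <- .stratifiedFolds(y, spec@nOuterFolds)
      for (f in seq_len(spec@nOuterFolds)) {
        test <- which(folds == f)
        pool <- which(folds != f)
        missing <- setdiff(lev, unique(as.character(y[pool])))
        if (length(missing))
          stop("class(es) absent from training fold ", f, ": ",
               paste(missing, collapse = ", "))
        tri <- if (spec@balanceTraining)
          .balancedIdx(y, pool, spec@trainFraction) else pool
        xtr <- x[tri, , drop = FALSE]; ytr <- y[tri]
        if (blind) xtr <- .shuffleTrainX(xtr, ytr, blindSeed + f)
        if (f == 1L) chosen <- .selectC(xtr, ytr, spec)
        fit <- .fitClassifier(xtr, ytr, spec, chosen)
        pred <- .predictClassifier(fit, x[test, , drop = FALSE])
        conf <- conf + unclass(table(factor(y[test], lev),
                                     factor(pred, lev)))
        foldAcc <- c(foldAcc, mean(pred == y[test]))
        nTrain <- c(nTrain, length(tri)); nTest <- c(nTest, length(test))
      }
    } else {
      n <- nrow(x)
      stopifnot(n >= 5)
      tri <- sample.int(n, floor(spec@trainFraction * n))
      test <- setdiff(seq_len(n), tri)
      if (spec@balanceTraining)
        tri <- .balancedIdx(y, tri, spec@trainFraction)
      missing <- setdiff(lev, unique(as.character(y[tri])))
      if (length(missing))
        stop("class(es) absent from the training set: ",
             paste(missing, collapse = ", "))
      xtr <- x[tri, , drop = FALSE]; ytr <- y[tri]
      if (blind) xtr <- .shuffleTrainX(xtr, ytr, blindSeed)
      chosen <- .selectC(xtr, ytr, spec)
      fit <- .fitClassifier(xtr, ytr, spec, chosen)
      pred <- .predictClassifier(fit, x[test, , drop = FALSE])
      conf <- conf + unclass(table(factor(y[test], lev), factor(pred, lev)))
      foldAcc <- mean(pred == y[test])
      nTrain <- length(tri); nTest <- length(test)
    }
  })

  storage.mode(conf) <- "double"
  perClass <- diag(conf) / rowSums(conf)
  new("DecodingResult",
      accuracy = sum(diag(conf)) / sum(conf),
      perClassAccuracy = perClass, foldAccuracy = foldAcc,
      chosenC = chosen, confusion = conf,
      nTrain = as.integer(nTrain), nTest = as.integer(nTest),
      classifier = spec@classifier)
})
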