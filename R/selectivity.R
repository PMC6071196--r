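#' @include AllClasses.R
NULL

#' Per-neuron mean responses by grating condition
#'
#' Averages, for every neuron, the per-trial responses (mean \eqn{\Delta F/F}
#' during the grating presentation) over the repeats of each
#' (direction, temporal frequency) condition.
#'
#' @param ds a \linkS4class{FeatureDataset} from
#'   \code{\link{segmentGratingTrials}} or
#'   \code{\link{simulateTrialResponses}} (must carry \code{direction_deg}
#'   and \code{temporal_freq_hz} in \code{colData()}). Use unnormalized
#'   responses: the indices are ratio-based, so the z-score shift distorts
#'   them.
#' @return A 3-d array neurons x directions x temporal frequencies, with
#'   dimnames giving neuron ids, directions (degrees) and frequencies (Hz).
#' @export
conditionMeans <- function(ds) {
  stopifnot(is(ds, "FeatureDataset"))
  cd <- colData(ds)
  if (!all(c("direction_deg", "temporal_freq_hz") %in% colnames(cd)))
    stop("dataset lacks direction_deg / temporal_freq_hz metadata")
  dirs <- sort(unique(cd$direction_deg))
  tfs <- sort(unique(cd$temporal_freq_hz))
  x <- featureMatrix(ds)
  out <- array(NA_real_, c(nrow(x), length(dirs), length(tfs)),
               dimnames = list(rownames(x), dirs, tfs))
  missing <- character()
  for (di in seq_along(dirs)) for (fi in seq_along(tfs)) {
    idx <- which(cd$direction_deg == dirs[di] &
                   cd$temporal_freq_hz == tfs[fi])
    if (!length(idx))
      missing <- c(missing, sprintf("(%g deg, %g Hz)", dirs[di], tfs[fi]))
    else
      out[, di, fi] <- rowMeans(x[, idx, drop = FALSE])
  }
  if (length(missing))
    stop("conditions with no trials: ", paste(missing, collapse = ", "))
  out
}

#' Preferred grating condition of one neuron
#'
#' The condition evoking the largest mean response; ties are broken toward the
#' lowest direction, then the lowest temporal frequency.
#'
#' @param table matrix directions x temporal frequencies of mean responses
#'   (dimnames = condition values), e.g. one slice of
#'   \code{\link{conditionMeans}}.
#' @return Named numeric vector \code{c(direction, tf)}.
#' @export
preferredCondition <- function(table) {
  stopifnot(is.matrix(table), !anyNA(table))
  dirs <- as.numeric(rownames(table))
  tfs <- as.numeric(colnames(table))
  hits <- which(table == max(table), arr.ind = TRUE)
  cand <- data.frame(dir = dirs[hits[, 1]], tf = tfs[hits[, 2]])
  cand <- cand[order(cand$dir, cand$tf), , drop = FALSE]
  c(direction = cand$dir[1], tf = cand$tf[1])
}

#' Orientation and direction selectivity indices
#'
#' From a neuron's condition-mean table, computes
#' \deqn{OSI = \frac{R_{pref} - R_{orth}}{R_{pref} + R_{orth}}, \qquad
#'       DSI = \frac{R_{pref} - R_{null}}{R_{pref} + R_{null}},}
#' where \eqn{R_{pref}} is the mean response at the preferred
#' (direction, temporal frequency) condition, \eqn{R_{orth}} the mean response
#' to the two orthogonal directions (preferred +/- 90 degrees) at the
#' preferred frequency, and \eqn{R_{null}} the response to the opposite
#' direction. Because \eqn{\Delta F/F} can be negative, both indices can
#' exceed 1 or be negative; a zero denominator yields \code{NA}.
#'
#' @param table matrix directions x temporal frequencies of mean responses.
#' @return Named list: \code{OSI}, \code{DSI}, \code{Rpref}, \code{Rorth},
#'   \code{Rnull}, \code{prefDirection}, \code{prefTf}.
#' @export
#' @examples
#' m <- matrix(c(1, 0, 0, 0), 4, 1,
#'             dimnames = list(c(0, 90, 180, 270), 1))
#' computeOsiDsi(m)[c("OSI", "DSI")]
computeOsiDsi <- function(table) {
  pref <- preferredCondition(table)
  dirs <- as.numeric(rownames(table))
  tfi <- match(pref["tf"], as.numeric(colnames(table)))
  resp <- function(d) table[match(d %% 360, dirs), tfi]
  rPref <- resp(pref["direction"])
  rOrth <- mean(c(resp(pref["direction"] + 90),
                  resp(pref["direction"] - 90)))
  rNull <- resp(pref["direction"] + 180)
  safeRatio <- function(num, den) if (abs(den) < .Machine$double.eps)
    NA_real_ else num / den
  list(OSI = safeRatio(rPref - rOrth, rPref + rOrth),
       DSI = safeRatio(rPref - rNull, rPref + rNull),
       Rpref = unname(rPref), Rorth = unname(rOrth), Rnull = unname(rNull),
       prefDirection = unname(pref["direction"]), prefTf = unname(pref["tf"]))
}

#' Per-neuron selectivity table
#'
#' Computes \code{\link{computeOsiDsi}} for every neuron of a grating feature
#' dataset and flags out-of-range values: following the exclusion rule, OSI or
#' DSI values below 0 or above 2 (or undefined) are marked excluded; the
#' boundary values 0 and 2 are retained.
#'
#' @param ds a grating \linkS4class{FeatureDataset} (unnormalized responses).
#' @return data.frame with columns \code{neuron_id}, \code{pref_dir},
#'   \code{pref_tf}, \code{Rpref}, \code{Rorth}, \code{Rnull}, \code{OSI},
#'   \code{DSI}, \code{excluded_osi}, \code{excluded_dsi}.
#' @export
selectivityTable <- function(ds) {
  cm <- conditionMeans(ds)
  rows <- lapply(seq_len(dim(cm)[1]), function(i) {
    s <- computeOsiDsi(cm[i, , , drop = TRUE])
    data.frame(neuron_id = dimnames(cm)[[1]][i],
               pref_dir = s$prefDirection, pref_tf = s$prefTf,
               Rpref = s$Rpref, Rorth = s$Rorth, Rnull = s$Rnull,
               OSI = s$OSI, DSI = s$DSI)
  })
  out <- do.call(rbind, rows)
  oob <- function(v) !is.finite(v) | v < 0 | v > 2
  out$excluded_osi <- oob(out$OSI)
  out$excluded_dsi <- oob(out$DSI)
  out
}

#' Apply the selectivity-index exclusion rule
#'
#' Keeps values in the closed interval \eqn{[0, 2]}; values below 0, above 2,
#' or non-finite are excluded and counted.
#'
#' @param values numeric vector of OSI or DSI values.
#' @return List: \code{kept} (the retained values), \code{nExcludedLow},
#'   \code{nExcludedHigh}, \code{nExcludedUndefined}.
#' @export
#' @examples
#' applyExclusions(c(-0.1, 0.5, 2.5, 2.0, 0))
applyExclusions <- function(values) {
  undef <- !is.finite(values)
  low <- !undef & values < 0
  high <- !undef & values > 2
  list(kept = values[!(undef | low | high)],
       nExcludedLow = sum(low), nExcludedHigh = sum(high),
       nExcludedUndefined = sum(undef))
}

#' Group-averaged selectivity
#'
#' Mean and standard error of the non-excluded index values per group (e.g.
#' visual area or imaging-depth group). A single-neuron group is reported
#' with SEM 0 and flagged; an empty group is reported with \code{NA} mean.
#'
#' @param tbl a \code{\link{selectivityTable}} data.frame.
#' @param grouping group label per neuron (same order as \code{tbl}).
#' @param metric \code{"OSI"} or \code{"DSI"}.
#' @return data.frame with columns \code{group}, \code{n}, \code{mean},
#'   \code{sem}, \code{degenerate}.
#' @export
groupAverage <- function(tbl, grouping, metric = c("OSI", "DSI")) {
  metric <- match.arg(metric)
  stopifnot(length(grouping) == nrow(tbl))
  excl <- if (metric == "OSI") tbl$excluded_osi else tbl$excluded_dsi
  v <- tbl[[metric]]
  out <- lapply(unique(as.character(grouping)), function(g) {
    vv <- v[grouping == g & !excl]
    n <- length(vv)
    data.frame(group = g, n = n,
               mean = if (n) mean(vv) else NA_real_,
               sem = if (n > 1) stats::sd(vv) / sqrt(n)
                     else if (n == 1) 0 else NA_real_,
               degenerate = n <= 1)
  })
  do.call(rbind, out)
}

#' Imaging-depth groups
#'
#' Sorts recording depths (micrometers) into the four canonical groups
#' 175, 265-300, 325-350 and 365-435.
#'
#' @param depthUm numeric vector of depths in micrometers.
#' @return Factor with the four group labels.
#' @export
#' @examples
#' depthGroup(c(175, 300, 350, 435))
depthGroup <- function(depthUm) {
  cut(depthUm, breaks = c(-Inf, 220, 312.5, 357.5, Inf),
      labels = c("175", "265-300", "325-350", "365-435"))
}
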