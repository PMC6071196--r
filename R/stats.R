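#' @include AllClasses.R
NULL

#' Tukey honest-significant-difference comparisons
#'
#' All pairwise comparisons of group means with studentized-range adjustment
#' at family level 0.05, as used for comparing decoding accuracies between
#' visual areas, depth groups or stimulus classes (typically on per-population
#' accuracies extrapolated to 128 neurons).
#'
#' @param groups named list of numeric vectors (one per group, each with at
#'   least 2 values).
#' @param conf.level family confidence level.
#' @return data.frame with columns \code{group_i}, \code{group_j},
#'   \code{mean_diff}, \code{adjusted_p}, \code{significant}; attribute
#'   \code{method = "tukey"}.
#' @export
#' @examples
#' tukeyAllPairs(list(a = rnorm(10), b = rnorm(10, 3), c = rnorm(10)))
tukeyAllPairs <- function(groups, conf.level = 0.95) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  if (any(lengths(groups) < 2L))
    stop("every group needs at least 2 values")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
  if (stats::var(df$value) == 0)
    stop("all values identical; comparisons are degenerate")
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit, conf.level = conf.level)$group
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(
    group_i = vapply(pairs, `[`, character(1), 1L),
    group_j = vapply(pairs, `[`, character(1), 2L),
    mean_diff = unname(tk[, "diff"]),
    adjusted_p = unname(tk[, "p adj"]),
    row.names = NULL)
  out$significant <- out$adjusted_p < (1 - conf.level)
  attr(out, "method") <- "tukey"
  out
}

#' One-sided Welch t tests against a reference group, Holm-adjusted
#'
#' Compares each group to a common reference with a one-sided Welch
#' (unequal-variance) t test and adjusts the family of p values with Holm's
#' method. \code{alternative = "greater"} tests whether the group mean exceeds
#' the reference mean; \code{"less"} the opposite.
#'
#' @param reference numeric vector of the reference group.
#' @param others named list of numeric vectors.
#' @param alternative direction of the alternative hypothesis, for the group
#'   relative to the reference.
#' @param level significance level applied to the adjusted p values.
#' @return data.frame with columns \code{group_i} (the group),
#'   \code{group_j} (\code{"reference"}), \code{mean_diff} (group - reference),
#'   \code{t}, \code{p}, \code{adjusted_p}, \code{significant}; attribute
#'   \code{method = "one_sided_t_adjusted"}.
#' @export
oneSidedTAdjusted <- function(reference, others,
                              alternative = c("greater", "less"),
                              level = 0.05) {
  alternative <- match.arg(alternative)
  stopifnot(is.list(others), length(others) >= 1L, length(reference) >= 2L)
  if (is.null(names(others))) names(others) <- seq_along(others)
  if (any(lengths(others) < 2L)) stop("every group needs at least 2 values")
  tests <- lapply(others, function(x)
    stats::t.test(x, reference, alternative = alternative, var.equal = FALSE))
  p <- vapply(tests, function(t) t$p.value, numeric(1))
  out <- data.frame(
    group_i = names(others), group_j = "reference",
    mean_diff = vapply(others, mean, numeric(1)) - mean(reference),
    t = vapply(tests, function(t) unname(t$statistic), numeric(1)),
    p = unname(p),
    adjusted_p = unname(stats::p.adjust(p, method = "holm")),
    row.names = NULL)
  out$significant <- out$adjusted_p < level
  attr(out, "method") <- "one_sided_t_adjusted"
  out
}

#' Paired t test
#'
#' Standard paired t test on the differences \code{x - y}:
#' \eqn{t = \bar d / (s_d / \sqrt{n})} with \eqn{n - 1} degrees of freedom
#' and a two-sided p value. Zero-variance differences are an error.
#'
#' @param x,y paired numeric vectors of equal length (>= 2).
#' @return List with \code{t}, \code{p}, \code{df}, \code{meanDiff}.
#' @export
#' @examples
#' pairedT(c(2, 4, 6), c(1, 2, 3))$t  # differences (1, 2, 3) -> 3.464
pairedT <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  sdd <- stats::sd(d)
  if (!is.finite(sdd) || sdd == 0)
    stop("paired differences have zero variance; t is undefined")
  n <- length(d)
  tval <- mean(d) / (sdd / sqrt(n))
  list(t = tval, p = 2 * stats::pt(-abs(tval), df = n - 1),
       df = n - 1L, meanDiff = mean(d))
}
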