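#' Construct a GrayHistogram
#'
#' @param probs numeric vector of bin probabilities (length L >= 2).
#' @param totalPixels number of pixels the probabilities were tallied from.
#' @return a \linkS4class{GrayHistogram}.
#' @examples
#' h <- grayHistogram(rep(1/4, 4), 100)
#' histProbs(h)
#' @export
grayHistogram <- function(probs, totalPixels = 0L) {
  new("GrayHistogram", probs = as.numeric(probs),
      totalPixels = as.integer(totalPixels))
}

#' Construct a ThresholdSet
#'
#' Canonicalizes on entry: values are sorted ascending and clamped to the
#' valid search domain \eqn{[1, L-1]}. Duplicated floors are left in place;
#' objective evaluation collapses them (the empty class contributes 0).
#'
#' @param values numeric vector of thresholds (gray-level units).
#' @param nLevels number of gray levels L (default 256).
#' @return a \linkS4class{ThresholdSet}.
#' @examples
#' thresholdSet(c(180.2, 63.7))
#' @export
thresholdSet <- function(values, nLevels = 256L) {
  L <- as.integer(nLevels)
  v <- sort(as.numeric(values))
  v <- pmin(pmax(v, 1), L - 1L)
  new("ThresholdSet", values = v, nLevels = L)
}

#' Compute the normalized gray-level histogram of an image
#'
#' Tallies pixel counts per gray level \eqn{j \in \{0, \ldots, L-1\}} and
#' normalizes by the pixel count, producing \eqn{p_j}, the probability mass
#' of level \eqn{j}.
#'
#' @param image numeric or integer matrix of 8-bit intensities in
#'   \code{0..nLevels-1}.
#' @param nLevels number of gray levels (default 256).
#' @return a \linkS4class{GrayHistogram}.
#' @examples
#' img <- matrix(c(0L, 255L), 1, 2)
#' histProbs(computeHistogram(img))[c(1, 256)]
#' @export
computeHistogram <- function(image, nLevels = 256L) {
  L <- as.integer(nLevels)
  v <- as.vector(image)
  if (length(v) == 0L) stop("empty input")
  if (anyNA(v)) stop("missing values in image")
  if (any(v < 0) || any(v > L - 1L)) stop("value outside gray range")
  counts <- tabulate(as.integer(round(v)) + 1L, nbins = L)
  grayHistogram(counts / length(v), length(v))
}

#' Rebin a histogram to fewer gray levels
#'
#' Aggregates adjacent bins into \code{nOut} equal groups, preserving total
#' probability. Used to build small instances on which exhaustive search
#' over many thresholds is feasible.
#'
#' @param hist a \linkS4class{GrayHistogram}.
#' @param nOut target number of levels; must divide the current level count.
#' @return a \linkS4class{GrayHistogram} with \code{nOut} bins.
#' @export
rebinHistogram <- function(hist, nOut = 32L) {
  stopifnot(is(hist, "GrayHistogram"))
  L <- length(hist@probs)
  nOut <- as.integer(nOut)
  if (L %% nOut != 0L) stop("nOut must divide the current number of levels")
  f <- L %/% nOut
  p <- vapply(seq_len(nOut),
              function(i) sum(hist@probs[((i - 1L) * f + 1L):(i * f)]),
              numeric(1))
  grayHistogram(p, hist@totalPixels)
}

## --- internal fast path -----------------------------------------------------
##
## Objective evaluation is on the hot path of every optimizer (N*(Tmax+1)
## calls per run), so the heavy lifting uses prefix sums precomputed once per
## histogram: cp[j+1] = sum p_0..p_{j-1}, cs likewise for j*p_j.

.histCache <- function(p) {
  L <- length(p)
  j <- seq.int(0L, L - 1L)
  list(cp = c(0, cumsum(p)), cs = c(0, cumsum(j * p)),
       muT = sum(j * p), L = L)
}

## tf: integer floored thresholds, sorted, in 1..L-1, duplicates allowed
## (duplicated floors yield empty classes contributing 0).
.otsuJfast <- function(cache, tf) {
  u <- c(tf, cache$L - 1L)          # upper bin (0-based, inclusive) per class
  lo <- c(0L, tf + 1L)              # lower bin per class
  w <- cache$cp[u + 2L] - cache$cp[lo + 1L]
  s <- cache$cs[u + 2L] - cache$cs[lo + 1L]
  nz <- w > 0
  m <- numeric(length(w))
  m[nz] <- s[nz] / w[nz]
  sum(w[nz] * (m[nz] - cache$muT)^2)
}

## evaluate a population matrix (N x d of real positions) against a cache
.evalPopulation <- function(cache, positions) {
  apply(positions, 1L, function(x) .otsuJfast(cache, sort(as.integer(floor(x)))))
}

#' Evaluate the Otsu between-class variance criterion
#'
#' Computes \eqn{J(T) = \sum_{i=1}^{k+1} \omega_i (\mu_i - \mu_T)^2} for the
#' class partition induced by the (floored) thresholds: class \eqn{i} is the
#' bin range \eqn{\lfloor t_{i-1}\rfloor < j \le \lfloor t_i\rfloor} with
#' \eqn{t_0}-boundary at bin 0 and \eqn{t_{k+1} = L-1}. \eqn{\omega_i} is the
#' probability mass of class \eqn{i} and \eqn{\mu_i} its mean gray level;
#' empty classes contribute exactly 0 (their mean is reported as 0 by
#' convention, avoiding 0/0). The within-class variance is returned alongside
#' and satisfies \code{J + within = total variance}.
#'
#' @param hist a \linkS4class{GrayHistogram}.
#' @param thresholds a \linkS4class{ThresholdSet} (or numeric vector, coerced
#'   with \code{nLevels} taken from the histogram).
#' @return an \linkS4class{ObjectiveBreakdown}.
#' @examples
#' p <- numeric(256); p[c(51, 201)] <- 0.5   # mass at levels 50 and 200
#' h <- grayHistogram(p, 2)
#' objectiveValue(otsuObjective(h, 100))     # 5625
#' @export
otsuObjective <- function(hist, thresholds) {
  stopifnot(is(hist, "GrayHistogram"))
  L <- length(hist@probs)
  if (!is(thresholds, "ThresholdSet")) thresholds <- thresholdSet(thresholds, L)
  if (nLevels(thresholds) != L) stop("threshold nLevels does not match histogram")
  p <- hist@probs
  cache <- .histCache(p)
  tf <- sort(as.integer(floor(thresholds@values)))
  tf <- unique(tf)                       # collapse duplicated floors
  u <- c(tf, L - 1L)
  lo <- c(0L, tf + 1L)
  w <- cache$cp[u + 2L] - cache$cp[lo + 1L]
  s <- cache$cs[u + 2L] - cache$cs[lo + 1L]
  nz <- w > 0
  m <- numeric(length(w))
  m[nz] <- s[nz] / w[nz]
  J <- sum(w[nz] * (m[nz] - cache$muT)^2)
  jj <- seq.int(0L, L - 1L)
  lab <- findInterval(jj, tf + 0.5) + 1L  # class index per bin
  within <- sum(p * (jj - m[lab])^2 * as.numeric(w[lab] > 0))
  new("ObjectiveBreakdown", J = J, classProbs = w, classMeans = m,
      globalMean = cache$muT, withinClassVariance = within,
      thresholds = thresholds)
}

#' Exhaustive search for the optimal threshold set
#'
#' Enumerates every strictly increasing integer threshold combination in
#' \eqn{\{1, \ldots, L-1\}^k} and returns the one maximizing the Otsu
#' criterion. Serves as the ground-truth oracle for validating the
#' metaheuristics on small instances. Ties are broken by the
#' lexicographically smallest threshold vector (enumeration order is
#' lexicographic, so the first maximum wins).
#'
#' @param hist a \linkS4class{GrayHistogram}.
#' @param k number of thresholds (>= 1).
#' @param maxCombinations guard cap on \eqn{\binom{L-1}{k}} (default 1e6).
#' @return list with \code{thresholds} (a \linkS4class{ThresholdSet} of
#'   integers) and \code{J}, the optimum.
#' @examples
#' h <- grayHistogram(rep(0.25, 4), 16)   # uniform over 4 levels
#' bruteForceThresholds(h, 1)$J           # 1.0 at t = 1
#' @export
bruteForceThresholds <- function(hist, k, maxCombinations = 1e6) {
  stopifnot(is(hist, "GrayHistogram"), k >= 1)
  k <- as.integer(k)
  L <- length(hist@probs)
  nc <- choose(L - 1L, k)
  if (nc > maxCombinations) stop("instance too large for oracle")
  cache <- .histCache(hist@probs)
  cmb <- utils::combn(L - 1L, k)          # lexicographic column order
  J <- apply(cmb, 2L, function(tf) .otsuJfast(cache, tf))
  best <- which.max(J)                    # first max = lexicographically smallest
  list(thresholds = thresholdSet(cmb[, best], L), J = J[best])
}
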