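#' @import methods
NULL

#' Normalized gray-level histogram
#'
#' Container for the normalized histogram of an 8-bit intensity image: a
#' length-\code{L} vector of bin probabilities \eqn{p_j} (one per gray level
#' \eqn{j = 0, \ldots, L-1}) together with the pixel count it was tallied
#' from. The histogram is the sole input to the Otsu between-class variance
#' objective; all optimizers operate on it, never on the pixel grid.
#'
#' @slot probs numeric vector of bin probabilities, nonnegative, summing to 1
#'   (within 1e-9) whenever \code{totalPixels > 0}.
#' @slot totalPixels nonnegative integer, number of pixels tallied.
#'
#' @seealso [computeHistogram()], [otsuObjective()], [bruteForceThresholds()]
#' @export
setClass("GrayHistogram",
  representation(probs = "numeric", totalPixels = "integer"),
  validity = function(object) {
    p <- object@probs
    if (length(p) < 2L) return("histogram needs at least 2 gray levels")
    if (anyNA(p) || any(p < 0)) return("bin probabilities must be >= 0 and non-missing")
    if (length(object@totalPixels) != 1L || is.na(object@totalPixels) ||
        object@totalPixels < 0L) {
      return("totalPixels must be a single nonnegative integer")
    }
    if (object@totalPixels > 0L && abs(sum(p) - 1) > 1e-9) {
      return("bin probabilities must sum to 1 within 1e-9")
    }
    TRUE
  }
)

#' Sorted set of real-valued thresholds
#'
#' A set of \code{k} real thresholds \eqn{t_1 < t_2 < \ldots < t_k} on the
#' gray-level axis, partitioning \eqn{0, \ldots, L-1} into \eqn{k+1} classes.
#' The search domain is continuous within \eqn{[1, L-1]}; evaluation of the
#' Otsu criterion floors each threshold because any real value between two
#' integer bins induces the identical partition (the objective is
#' piecewise-constant).
#'
#' Class \eqn{i} covers bins \eqn{\lfloor t_{i-1}\rfloor < j \le \lfloor
#' t_i\rfloor}, with class 1 starting at bin 0 and class \eqn{k+1} ending at
#' \eqn{L-1}.
#'
#' @slot values numeric vector, sorted ascending, each in \eqn{[1, L-1]}.
#' @slot nLevels integer, number of gray levels \code{L} (default 256).
#'
#' @seealso [thresholdSet()], [otsuObjective()], [applyThresholds()]
#' @export
setClass("ThresholdSet",
  representation(values = "numeric", nLevels = "integer"),
  validity = function(object) {
    v <- object@values
    L <- object@nLevels
    if (length(L) != 1L || is.na(L) || L < 2L) return("nLevels must be a single integer >= 2")
    if (length(v) < 1L) return("at least one threshold required")
    if (anyNA(v) || any(!is.finite(v))) return("thresholds must be finite")
    if (is.unsorted(v)) return("thresholds must be sorted ascending")
    if (any(v < 1) || any(v > L - 1)) return("thresholds must lie in [1, nLevels-1]")
    TRUE
  }
)

#' Otsu objective decomposition
#'
#' Full breakdown of the between-class variance criterion for one
#' (histogram, threshold set) pair: the objective value \eqn{J = \sum_i
#' \omega_i (\mu_i - \mu_T)^2}, the per-class probabilities \eqn{\omega_i}
#' and means \eqn{\mu_i}, the global mean \eqn{\mu_T}, and the complementary
#' within-class variance. The decomposition \code{J + withinClassVariance =
#' total histogram variance} holds to numerical precision.
#'
#' @slot J between-class variance (squared gray-level units).
#' @slot classProbs numeric, per-class probabilities (sum 1).
#' @slot classMeans numeric, per-class mean intensities (0 for empty classes).
#' @slot globalMean global mean intensity.
#' @slot withinClassVariance probability-weighted within-class variance.
#' @slot thresholds the canonical \linkS4class{ThresholdSet} evaluated.
#'
#' @seealso [otsuObjective()]
#' @export
setClass("ObjectiveBreakdown",
  representation(J = "numeric", classProbs = "numeric", classMeans = "numeric",
                 globalMean = "numeric", withinClassVariance = "numeric",
                 thresholds = "ThresholdSet"))

#' Per-iteration optimizer trace
#'
#' Records, for one optimizer run, the best objective value after each
#' iteration, the phase each iteration belonged to (\code{"SCSO"} or
#' \code{"WOA"}; baselines use their own name), and the total number of
#' objective evaluations spent. The best-fitness sequence is non-decreasing
#' (elitism) and the evaluation count equals \eqn{N (T_{max} + 1)} exactly:
#' \eqn{N} initialization evaluations plus \eqn{N} per iteration.
#'
#' @slot bestFitness numeric, length \code{Tmax}, non-decreasing.
#' @slot phase character, length \code{Tmax}, phase label per iteration.
#' @slot nEvals integer, total objective evaluations.
#'
#' @seealso [runSCSOWOA()], [runBaseline()], [traceFrame()]
#' @export
setClass("FitnessTrace",
  representation(bestFitness = "numeric", phase = "character", nEvals = "integer"),
  validity = function(object) {
    if (length(object@bestFitness) != length(object@phase)) {
      return("bestFitness and phase must have equal length")
    }
    if (length(object@bestFitness) > 1L &&
        any(diff(object@bestFitness) < 0)) {
      return("bestFitness must be non-decreasing")
    }
    TRUE
  }
)

#' Result of one optimizer run
#'
#' @slot thresholds canonical best \linkS4class{ThresholdSet} found.
#' @slot J objective value of the best threshold set.
#' @slot trace \linkS4class{FitnessTrace} of the run.
#' @slot algorithm character, algorithm name.
#' @slot seed integer seed the run was reproducibly started from.
#' @slot extras list of optional diagnostics (logged RNG draws when the
#'   config requests them).
#'
#' @seealso [runSCSOWOA()], [runBaseline()]
#' @export
setClass("SwarmFit",
  representation(thresholds = "ThresholdSet", J = "numeric",
                 trace = "FitnessTrace", algorithm = "character",
                 seed = "integer", extras = "list"))

#' Multilevel segmentation of an image
#'
#' A label map assigning each pixel its threshold class (0-based, monotone
#' in intensity) and the class-mean reconstruction: each pixel replaced by
#' the rounded mean intensity of its class, the standard "segmented image"
#' fed to full-reference quality metrics in multilevel-thresholding work.
#'
#' @slot labelMap integer matrix of class indices in \code{0..k}.
#' @slot reconstruction numeric matrix of 8-bit class-representative values.
#' @slot thresholds the canonical \linkS4class{ThresholdSet} applied.
#'
#' @seealso [applyThresholds()]
#' @export
setClass("SegmentationResult",
  representation(labelMap = "matrix", reconstruction = "matrix",
                 thresholds = "ThresholdSet"))

setMethod("show", "GrayHistogram", function(object) {
  nz <- sum(object@probs > 0)
  cat("GrayHistogram:", length(object@probs), "levels,",
      object@totalPixels, "pixels,", nz, "occupied bins\n")
})

setMethod("show", "ThresholdSet", function(object) {
  cat("ThresholdSet: k =", length(object@values), "on", object@nLevels,
      "levels\n  ", paste(signif(object@values, 6), collapse = ", "), "\n")
})

setMethod("show", "ObjectiveBreakdown", function(object) {
  cat("ObjectiveBreakdown: J =", format(object@J), "\n")
  cat("  global mean:", format(object@globalMean),
      " within-class var:", format(object@withinClassVariance), "\n")
  cat("  class probs:", paste(signif(object@classProbs, 4), collapse = ", "), "\n")
})

setMethod("show", "FitnessTrace", function(object) {
  n <- length(object@bestFitness)
  cat("FitnessTrace:", n, "iterations,", object@nEvals, "evaluations\n")
  if (n > 0L) {
    cat("  phases:", paste(rle(object@phase)$values,
                           rle(object@phase)$lengths, collapse = " | "), "\n")
    cat("  final best:", format(object@bestFitness[n]), "\n")
  }
})

setMethod("show", "SwarmFit", function(object) {
  cat("SwarmFit [", object@algorithm, "] seed", object@seed, "\n")
  cat("  J =", format(object@J), " thresholds:",
      paste(signif(object@thresholds@values, 6), collapse = ", "), "\n")
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult:", paste(dim(object@labelMap), collapse = " x "),
      "pixels,", length(object@thresholds@values) + 1L, "classes\n")
})
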