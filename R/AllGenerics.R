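#' Accessors for SwarmThresh objects
#'
#' Small accessor family following Bioconductor convention: slots are read
#' through generics, never with \code{@}.
#'
#' @param object an object of the documented classes.
#' @return the slot value; see individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("histProbs", function(object) standardGeneric("histProbs"))

#' @rdname accessors
#' @export
setGeneric("totalPixels", function(object) standardGeneric("totalPixels"))

#' @rdname accessors
#' @export
setGeneric("nLevels", function(object) standardGeneric("nLevels"))

#' @rdname accessors
#' @export
setGeneric("thresholdValues", function(object) standardGeneric("thresholdValues"))

#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))

#' @rdname accessors
#' @export
setGeneric("bestThresholds", function(object) standardGeneric("bestThresholds"))

#' @rdname accessors
#' @export
setGeneric("fitnessTrace", function(object) standardGeneric("fitnessTrace"))

#' @rdname accessors
#' @export
setGeneric("nEvaluations", function(object) standardGeneric("nEvaluations"))

#' @rdname accessors
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))

#' @rdname accessors
#' @export
setGeneric("reconstruction", function(object) standardGeneric("reconstruction"))

#' @rdname accessors
#' @export
setMethod("histProbs", "GrayHistogram", function(object) object@probs)

#' @rdname accessors
#' @export
setMethod("totalPixels", "GrayHistogram", function(object) object@totalPixels)

#' @rdname accessors
#' @export
setMethod("nLevels", "GrayHistogram", function(object) length(object@probs))

#' @rdname accessors
#' @export
setMethod("nLevels", "ThresholdSet", function(object) object@nLevels)

#' @rdname accessors
#' @export
setMethod("thresholdValues", "ThresholdSet", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("thresholdValues", "SwarmFit", function(object) object@thresholds@values)

#' @rdname accessors
#' @export
setMethod("objectiveValue", "ObjectiveBreakdown", function(object) object@J)

#' @rdname accessors
#' @export
setMethod("objectiveValue", "SwarmFit", function(object) object@J)

#' @rdname accessors
#' @export
setMethod("bestThresholds", "SwarmFit", function(object) object@thresholds)

#' @rdname accessors
#' @export
setMethod("fitnessTrace", "SwarmFit", function(object) object@trace)

#' @rdname accessors
#' @export
setMethod("nEvaluations", "FitnessTrace", function(object) object@nEvals)

#' @rdname accessors
#' @export
setMethod("nEvaluations", "SwarmFit", function(object) object@trace@nEvals)

#' @rdname accessors
#' @export
setMethod("labelMap", "SegmentationResult", function(object) object@labelMap)

#' @rdname accessors
#' @export
setMethod("reconstruction", "SegmentationResult", function(object) object@reconstruction)

#' Fitness trace as a data.frame
#'
#' Flattens a \linkS4class{FitnessTrace} to a data.frame with columns
#' \code{iteration}, \code{phase}, \code{best_fitness}, \code{n_evals}
#' (cumulative), the layout used for CSV trace files.
#'
#' @param trace a \linkS4class{FitnessTrace} or \linkS4class{SwarmFit}.
#' @return a data.frame with one row per iteration.
#' @export
traceFrame <- function(trace) {
  if (is(trace, "SwarmFit")) trace <- trace@trace
  stopifnot(is(trace, "FitnessTrace"))
  n <- length(trace@bestFitness)
  N0 <- if (n > 0L) trace@nEvals %/% (n + 1L) else trace@nEvals
  data.frame(
    iteration = seq_len(n),
    phase = trace@phase,
    best_fitness = trace@bestFitness,
    n_evals = N0 * (seq_len(n) + 1L)
  )
}
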