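#' Extract the named rate vector
#'
#' @param object A \linkS4class{RateParameters} or \linkS4class{DynamicsFit}.
#' @return Named numeric of length 6 (aHi, aLo, dHi, dLo, kHL, kLH).
#' @export
setGeneric("rates", function(object) standardGeneric("rates"))

#' @rdname rates
#' @export
setMethod("rates", "RateParameters", function(object) object@rates)

#' @rdname rates
#' @export
setMethod("rates", "DynamicsFit", function(object) object@params@rates)

#' Fit diagnostics accessor
#'
#' @param object A \linkS4class{DynamicsFit}.
#' @return List with \code{objective}, \code{lambda}, \code{iterations},
#'   \code{converged}, \code{rmse}, \code{nObsPairs}.
#' @export
setGeneric("diagnostics", function(object) standardGeneric("diagnostics"))

#' @rdname diagnostics
#' @export
setMethod("diagnostics", "DynamicsFit", function(object) object@diagnostics)

#' Hypothesis name accessor
#'
#' @param object A \linkS4class{HypothesisSpec} or \linkS4class{DynamicsFit}.
#' @return Character scalar.
#' @export
setGeneric("hypothesisName", function(object) standardGeneric("hypothesisName"))

#' @rdname hypothesisName
#' @export
setMethod("hypothesisName", "HypothesisSpec", function(object) object@name)

#' @rdname hypothesisName
#' @export
setMethod("hypothesisName", "DynamicsFit",
          function(object) object@hypothesis@name)

#' Measurement table accessor
#'
#' @param object A \linkS4class{TimeCourse} or
#'   \linkS4class{CompartmentTrajectories}.
#' @return The underlying long-format data.frame.
#' @export
setGeneric("measurements", function(object) standardGeneric("measurements"))

#' @rdname measurements
#' @export
setMethod("measurements", "TimeCourse", function(object) object@data)

#' @rdname measurements
#' @export
setMethod("measurements", "CompartmentTrajectories", function(object) object@data)

#' Gate threshold accessor
#'
#' @param object A \linkS4class{GateThresholds}.
#' @return Named numeric of per-marker thresholds (MFI units).
#' @export
setGeneric("thresholds", function(object) standardGeneric("thresholds"))

#' @rdname thresholds
#' @export
setMethod("thresholds", "GateThresholds", function(object) object@thresholds)

#' State label accessor
#'
#' @param object A \linkS4class{StateLabeling}.
#' @return Character vector of per-cell labels.
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))

#' @rdname stateLabels
#' @export
setMethod("stateLabels", "StateLabeling", function(object) object@labels)

setMethod("show", "RateParameters", function(object) {
  cat("RateParameters (per 12 h step)\n")
  print(round(object@rates, 6))
})

setMethod("show", "HypothesisSpec", function(object) {
  cat(sprintf("HypothesisSpec '%s'\n", object@name))
  if (length(object@fixes))
    cat("  fixed:", paste(sprintf("%s = %g", names(object@fixes),
                                  object@fixes), collapse = ", "), "\n")
  for (g in object@ties) cat("  tied: ", paste(g, collapse = " = "), "\n")
  cat("  dead-cell allocation:", object@allocation, "\n")
})

setMethod("show", "TimeCourse", function(object) {
  d <- object@data
  cat(sprintf("TimeCourse: %d records, %d wells, arms: %s\n",
              nrow(d), length(unique(d$well_id)),
              paste(unique(d$arm), collapse = ", ")))
  cat(sprintf("  timepoints (h): %s\n",
              paste(sort(unique(d$timepoint_h)), collapse = ", ")))
  cat(sprintf("  observed: %d/%d (control arm: %s)\n",
              sum(d$observed), nrow(d), object@controlArm))
})

setMethod("show", "CompartmentTrajectories", function(object) {
  d <- object@data
  cat(sprintf("CompartmentTrajectories (%s allocation): %d records, %d wells\n",
              object@hypothesis, nrow(d), length(unique(d$well_id))))
  if (any(d$floored, na.rm = TRUE))
    cat(sprintf("  %d live estimates floored at 0\n", sum(d$floored, na.rm = TRUE)))
})

setMethod("show", "DynamicsFit", function(object) {
  cat(sprintf("DynamicsFit under '%s' (lambda = %g)\n",
              object@hypothesis@name, object@diagnostics$lambda))
  print(round(object@params@rates, 6))
  cat(sprintf("  %d iterations, converged: %s, final objective %.6g\n",
              object@diagnostics$iterations, object@diagnostics$converged,
              tail(object@diagnostics$objective, 1)))
})

setMethod("show", "GateThresholds", function(object) {
  cat(sprintf("GateThresholds from %d pooled '%s' cells\n",
              object@nCells, object@controlArm))
  print(round(object@thresholds, 3))
})

setMethod("show", "StateLabeling", function(object) {
  cat(sprintf("StateLabeling '%s' over markers %s: %d cells\n",
              object@scheme, paste(object@markers, collapse = "/"),
              length(object@labels)))
  print(table(object@labels))
})
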