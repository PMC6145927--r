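#' @import methods
NULL

RATE_NAMES <- c("aHi", "aLo", "dHi", "dLo", "kHL", "kLH")

#' Per-step rates of the two-live-state birth/death/transition model
#'
#' Holds the six rate parameters of the discrete-time linear time-invariant
#' (LTI) population model on (K14hi live, K14lo live, dead): division
#' probabilities per step \code{aHi}, \code{aLo}; death probabilities
#' \code{dHi}, \code{dLo}; transition probabilities \code{kHL}
#' (K14hi to K14lo) and \code{kLH} (K14lo to K14hi). All rates are per-step
#' probabilities (one step = the sampling interval, 12 h by default) and must
#' lie in [0, 1]; per live state the net multiplier 1 + a - d - k_out must be
#' nonnegative so populations cannot go negative.
#'
#' @slot rates Named numeric of length 6 (aHi, aLo, dHi, dLo, kHL, kLH).
#' @export
setClass("RateParameters", representation(rates = "numeric"))

setValidity("RateParameters", function(object) {
  r <- object@rates
  if (!identical(names(r), RATE_NAMES))
    return(sprintf("rates must be named %s", paste(RATE_NAMES, collapse = ", ")))
  if (anyNA(r)) return("rates must not contain NA")
  if (any(r < 0 | r > 1)) return("all rates must lie in [0, 1]")
  if (1 + r["aHi"] - r["dHi"] - r["kHL"] < -1e-9)
    return("K14hi budget violated: 1 + aHi - dHi - kHL < 0")
  if (1 + r["aLo"] - r["dLo"] - r["kLH"] < -1e-9)
    return("K14lo budget violated: 1 + aLo - dLo - kLH < 0")
  TRUE
})

#' Construct rate parameters
#'
#' @param aHi,aLo Division probability per step for the K14hi / K14lo state.
#' @param dHi,dLo Death probability per step.
#' @param kHL Transition probability K14hi -> K14lo per step.
#' @param kLH Transition probability K14lo -> K14hi per step.
#' @return A \linkS4class{RateParameters} object.
#' @examples
#' rateParameters(aHi = 0.02, aLo = 0.02, dHi = 0.02, dLo = 0.02,
#'                kHL = 0.005, kLH = 0.2)
#' @export
rateParameters <- function(aHi = 0, aLo = 0, dHi = 0, dLo = 0,
                           kHL = 0, kLH = 0) {
  new("RateParameters",
      rates = c(aHi = unname(aHi), aLo = unname(aLo), dHi = unname(dHi),
                dLo = unname(dLo), kHL = unname(kHL), kLH = unname(kLH)))
}

#' Named hypothesis on the structure of drug-induced dynamics
#'
#' A hypothesis is a set of equality constraints on the six rates plus a rule
#' for allocating estimated dead cells to the measured state counts when
#' live compartments are estimated:
#' \describe{
#'   \item{darwinian_k14hi}{selective killing of K14lo only: kHL = kLH = 0,
#'     dHi = 0; all dead cells are subtracted from the measured K14lo count.}
#'   \item{transition_mediated}{equal per-capita death (dHi = dLo) with free
#'     transitions; dead cells are allocated proportionally to state counts.}
#'   \item{control}{unconstrained dynamics apart from shared proliferation;
#'     dead cells are split 50/50 between the two measured counts.}
#' }
#' The EdU-derived shared-proliferation constraint aHi = aLo is applied to all
#' built-in hypotheses (S-phase frequencies measured by EdU incorporation do
#' not differ between marker-high and marker-low cells under these
#' treatments) and can be dropped in custom specs.
#'
#' @slot name Character scalar.
#' @slot fixes Named numeric: rates pinned to fixed values (typically 0).
#' @slot ties List of character vectors: groups of rates constrained equal.
#' @slot allocation Dead-cell allocation rule: one of \code{"k14lo"},
#'   \code{"proportional"}, \code{"equal"}.
#' @export
setClass("HypothesisSpec",
         representation(name = "character", fixes = "numeric",
                        ties = "list", allocation = "character"))

setValidity("HypothesisSpec", function(object) {
  if (length(object@name) != 1L) return("name must be a single string")
  if (length(object@fixes) && !all(names(object@fixes) %in% RATE_NAMES))
    return("fixes must be named by rate parameters")
  if (!object@allocation %in% c("k14lo", "proportional", "equal"))
    return("allocation must be 'k14lo', 'proportional' or 'equal'")
  for (g in object@ties) {
    if (!is.character(g) || length(g) < 2L || !all(g %in% RATE_NAMES))
      return("each tie group must name >= 2 rate parameters")
    if (any(g %in% names(object@fixes)) && !all(g %in% names(object@fixes)))
      return("a tie group mixing fixed and free rates is inconsistent")
  }
  TRUE
})

#' Construct a hypothesis specification
#'
#' @param name Hypothesis label.
#' @param fixes Named numeric vector of rates pinned to constants.
#' @param ties List of character vectors of rates constrained equal.
#' @param allocation Dead-cell allocation rule (\code{"k14lo"},
#'   \code{"proportional"}, or \code{"equal"}).
#' @param sharedProliferation Apply the EdU constraint aHi = aLo (default TRUE).
#' @return A \linkS4class{HypothesisSpec}.
#' @export
hypothesisSpec <- function(name, fixes = numeric(0), ties = list(),
                           allocation = c("proportional", "k14lo", "equal"),
                           sharedProliferation = TRUE) {
  allocation <- match.arg(allocation)
  if (sharedProliferation &&
      !any(vapply(ties, function(g) all(c("aHi", "aLo") %in% g), logical(1))))
    ties <- c(ties, list(c("aHi", "aLo")))
  new("HypothesisSpec", name = name, fixes = fixes, ties = ties,
      allocation = allocation)
}

#' @rdname hypothesisSpec
#' @export
darwinianHypothesis <- function() {
  hypothesisSpec("darwinian_k14hi",
                 fixes = c(kHL = 0, kLH = 0, dHi = 0),
                 allocation = "k14lo")
}

#' @rdname hypothesisSpec
#' @export
transitionHypothesis <- function() {
  hypothesisSpec("transition_mediated",
                 ties = list(c("dHi", "dLo")),
                 allocation = "proportional")
}

#' @rdname hypothesisSpec
#' @export
controlHypothesis <- function() {
  hypothesisSpec("control", allocation = "equal")
}

#' Replicate-well time-course measurements
#'
#' Wraps the long-format measurement table produced downstream of image
#' cytometry: per well, arm, and timepoint, the gated K14hi and K14lo cell
#' counts (which include dead cells still present in the imaged field), the
#' measured death fraction (YO-PRO-1 positive over total), and an observation
#' flag (\code{observed = FALSE} marks illegible well x time records, whose
#' measurement columns are NA).
#'
#' @slot data data.frame with columns \code{well_id}, \code{arm},
#'   \code{timepoint_h}, \code{count_k14hi}, \code{count_k14lo},
#'   \code{death_fraction}, \code{observed}.
#' @slot controlArm Name of the vehicle arm (default "DMSO").
#' @export
setClass("TimeCourse",
         representation(data = "data.frame", controlArm = "character"))

.TC_COLS <- c("well_id", "arm", "timepoint_h", "count_k14hi", "count_k14lo",
              "death_fraction", "observed")

setValidity("TimeCourse", function(object) {
  d <- object@data
  miss <- setdiff(.TC_COLS, names(d))
  if (length(miss)) return(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  obs <- d$observed
  if (!is.logical(obs) || anyNA(obs)) return("observed must be logical, no NA")
  dfo <- d$death_fraction[obs]
  if (any(!is.na(dfo) & (dfo < 0 | dfo > 1)))
    return("observed death fractions must lie in [0, 1]")
  if (any(!is.na(d$count_k14hi[obs]) & d$count_k14hi[obs] < 0) ||
      any(!is.na(d$count_k14lo[obs]) & d$count_k14lo[obs] < 0))
    return("observed counts must be nonnegative")
  if (any(!d$observed[d$timepoint_h == ave(d$timepoint_h, d$arm, FUN = min)]))
    return("time-zero records must be observed (required initial conditions)")
  TRUE
})

#' Construct a TimeCourse from a measurement table
#'
#' @param data data.frame with the columns documented in
#'   \linkS4class{TimeCourse}.
#' @param controlArm Name of the vehicle-control arm present in \code{data}.
#' @return A \linkS4class{TimeCourse}.
#' @export
TimeCourse <- function(data, controlArm = "DMSO") {
  data <- as.data.frame(data)
  if (!"observed" %in% names(data)) data$observed <- TRUE
  new("TimeCourse", data = data, controlArm = controlArm)
}

#' Estimated live/dead compartment trajectories
#'
#' Per well and timepoint, the estimated number of K14hi live cells, K14lo
#' live cells, and (cumulative) dead cells, derived from a
#' \linkS4class{TimeCourse} under a hypothesis-specific dead-cell allocation
#' rule. Masked records carry NA and \code{observed = FALSE}. Within each
#' well the dead series is nondecreasing over observed timepoints.
#'
#' @slot data data.frame with columns \code{well_id}, \code{arm},
#'   \code{timepoint_h}, \code{nHi}, \code{nLo}, \code{nDead},
#'   \code{observed}, \code{floored}.
#' @slot hypothesis Name of the hypothesis whose allocation rule was used.
#' @export
setClass("CompartmentTrajectories",
         representation(data = "data.frame", hypothesis = "character"))

setValidity("CompartmentTrajectories", function(object) {
  d <- object@data
  need <- c("well_id", "arm", "timepoint_h", "nHi", "nLo", "nDead",
            "observed", "floored")
  miss <- setdiff(need, names(d))
  if (length(miss)) return(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  obs <- d$observed
  if (any(!is.na(d$nHi[obs]) & d$nHi[obs] < -1e-9) ||
      any(!is.na(d$nLo[obs]) & d$nLo[obs] < -1e-9) ||
      any(!is.na(d$nDead[obs]) & d$nDead[obs] < -1e-9))
    return("observed compartment estimates must be nonnegative")
  for (w in unique(d$well_id)) {
    dw <- d[d$well_id == w & d$observed, , drop = FALSE]
    dw <- dw[order(dw$timepoint_h), , drop = FALSE]
    if (is.unsorted(dw$nDead, na.rm = TRUE))
      return(sprintf("dead series must be nondecreasing within well %s", w))
  }
  TRUE
})

#' Fitted dynamics: rates plus diagnostics
#'
#' @slot params \linkS4class{RateParameters} at the (local) optimum.
#' @slot hypothesis \linkS4class{HypothesisSpec} under which the fit ran.
#' @slot diagnostics List: \code{objective} (value per iteration),
#'   \code{lambda}, \code{iterations}, \code{converged}, \code{rmse}
#'   (residual RMSE per compartment), \code{nObsPairs}.
#' @export
setClass("DynamicsFit",
         representation(params = "RateParameters",
                        hypothesis = "HypothesisSpec",
                        diagnostics = "list"))

setValidity("DynamicsFit", function(object) {
  obj <- object@diagnostics$objective
  if (length(obj) && any(diff(obj) > 1e-8 * (1 + abs(obj[-length(obj)]))))
    return("objective sequence must be nonincreasing")
  TRUE
})

#' Per-marker gate thresholds from vehicle-control cells
#'
#' A cell is called marker-high when its MFI strictly exceeds the marker's
#' threshold, defined as the arithmetic mean MFI over all pooled control-arm
#' cells.
#'
#' @slot thresholds Named numeric, one threshold (MFI units) per marker.
#' @slot controlArm Name of the control arm the thresholds came from.
#' @slot nCells Number of control cells pooled.
#' @export
setClass("GateThresholds",
         representation(thresholds = "numeric", controlArm = "character",
                        nCells = "integer"))

setValidity("GateThresholds", function(object) {
  if (is.null(names(object@thresholds)) || any(!nzchar(names(object@thresholds))))
    return("thresholds must be named by marker")
  if (any(object@thresholds < 0)) return("thresholds must be nonnegative")
  TRUE
})

#' Per-cell state labels under a named gating scheme
#'
#' @slot scheme Scheme name ("combinatorial" or "prominent").
#' @slot labels Character vector, one label per cell (scheme vocabulary).
#' @slot markers Markers used by the scheme, in gating order.
#' @export
setClass("StateLabeling",
         representation(scheme = "character", labels = "character",
                        markers = "character"))
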