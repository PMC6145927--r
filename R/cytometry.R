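# Gating and state-frequency computations applied downstream of image
# cytometry. The gating convention throughout: a cell is marker-"high" when
# its MFI strictly exceeds the marker's threshold (the mean MFI over pooled
# vehicle-control cells); ties are negative.

.MARKER_COLS <- c(K19 = "k19_mfi", K14 = "k14_mfi", VIM = "vim_mfi")

.checkMarkers <- function(cells, markers) {
  cols <- .MARKER_COLS[markers]
  if (anyNA(cols)) stop("unknown marker(s): ",
                        paste(markers[is.na(cols)], collapse = ", "))
  miss <- setdiff(cols, names(cells))
  if (length(miss)) stop("missing marker column(s): ",
                         paste(miss, collapse = ", "))
  cols
}

# Drop dying cells from gating computations when a dying flag exists
# (antibody staining is non-specific in dying cells).
.gateable <- function(cells, excludeDying = TRUE) {
  if (excludeDying && "dying" %in% names(cells))
    cells[!(cells$dying %in% 1), , drop = FALSE]
  else cells
}

#' Compute per-marker gate thresholds from the vehicle-control arm
#'
#' The threshold for each marker is the arithmetic mean of per-cell MFI over
#' all control-arm cells pooled across wells.
#'
#' @param cells Cell table (see \code{\link{generateCellTable}} for columns).
#' @param controlArm Name of the control arm in \code{cells$arm}.
#' @param markers Markers to gate (default K19, K14, VIM).
#' @param excludeDying Drop cells flagged \code{dying} before pooling.
#' @return A \linkS4class{GateThresholds}.
#' @export
computeGateThresholds <- function(cells, controlArm = "DMSO",
                                  markers = c("K19", "K14", "VIM"),
                                  excludeDying = TRUE) {
  cols <- .checkMarkers(cells, markers)
  ctrl <- .gateable(cells[cells$arm == controlArm, , drop = FALSE], excludeDying)
  if (nrow(ctrl) == 0L)
    stop(sprintf("control arm '%s' has no (gateable) cells", controlArm))
  th <- vapply(cols, function(cl) mean(ctrl[[cl]]), numeric(1))
  names(th) <- markers
  new("GateThresholds", thresholds = th, controlArm = controlArm,
      nCells = nrow(ctrl))
}

#' Assign combinatorial marker-positivity states
#'
#' Labels each cell by its +/- pattern over the ordered marker set (2^M
#' states; M = 3 gives the eight-state scheme). "High" is a strict
#' inequality against the threshold. The six-state primary-tumor scheme is
#' this scheme restricted to epithelial (K19+ or K14+) cells.
#'
#' @param cells Cell table.
#' @param gate A \linkS4class{GateThresholds} covering \code{markers}.
#' @param markers Ordered markers defining the pattern.
#' @param excludeDying Drop cells flagged \code{dying}.
#' @return A \linkS4class{StateLabeling} with labels like
#'   \code{"K19+/K14-/VIM+"}.
#' @export
assignCombinatorialStates <- function(cells, gate,
                                      markers = c("K19", "K14", "VIM"),
                                      excludeDying = TRUE) {
  stopifnot(is(gate, "GateThresholds"))
  cols <- .checkMarkers(cells, markers)
  th <- gate@thresholds
  if (!all(markers %in% names(th)))
    stop("gate does not cover all requested markers")
  cells <- .gateable(cells, excludeDying)
  pos <- vapply(markers, function(m) cells[[cols[[m]]]] > th[[m]],
                logical(nrow(cells)))
  pos <- matrix(pos, nrow = nrow(cells))
  labels <- apply(pos, 1L, function(p)
    paste0(markers, ifelse(p, "+", "-"), collapse = "/"))
  if (nrow(cells) == 0L) labels <- character(0)
  new("StateLabeling", scheme = "combinatorial", labels = labels,
      markers = markers)
}

#' Assign the four prominent differentiation states
#'
#' Priority partition over K19/K14/VIM gates: K14-high cells are
#' \code{K14hi} (regardless of other markers, so K19hi/K14hi cells are
#' included); otherwise VIM-high cells are \code{VIMhi}; otherwise K19-high
#' cells are \code{K19hi}; remaining cells are \code{TripleLow}. The
#' partition is exhaustive and exclusive.
#'
#' @inheritParams assignCombinatorialStates
#' @return A \linkS4class{StateLabeling} with labels in
#'   \code{c("K14hi", "VIMhi", "K19hi", "TripleLow")}.
#' @export
assignProminentStates <- function(cells, gate, excludeDying = TRUE) {
  stopifnot(is(gate, "GateThresholds"))
  markers <- c("K19", "K14", "VIM")
  cols <- .checkMarkers(cells, markers)
  th <- gate@thresholds
  if (!all(markers %in% names(th)))
    stop("gate must cover K19, K14 and VIM")
  cells <- .gateable(cells, excludeDying)
  k14 <- cells[[cols[["K14"]]]] > th[["K14"]]
  vim <- cells[[cols[["VIM"]]]] > th[["VIM"]]
  k19 <- cells[[cols[["K19"]]]] > th[["K19"]]
  labels <- ifelse(k14, "K14hi",
                   ifelse(vim, "VIMhi", ifelse(k19, "K19hi", "TripleLow")))
  if (nrow(cells) == 0L) labels <- character(0)
  new("StateLabeling", scheme = "prominent", labels = labels,
      markers = markers)
}

#' Collapse combinatorial labels by the prominent-state priority rule
#'
#' @param labels Character vector of \code{"K19x/K14x/VIMx"} labels.
#' @return Character vector of prominent-state labels.
#' @export
collapseToProminent <- function(labels) {
  ifelse(grepl("K14\\+", labels), "K14hi",
         ifelse(grepl("VIM\\+", labels), "VIMhi",
                ifelse(grepl("K19\\+", labels), "K19hi", "TripleLow")))
}

#' Per-group cell-state frequency table
#'
#' Within each group (combination of the grouping keys), the proportion of
#' each state is its cell count over the group total; states absent from a
#' group are reported with proportion 0 so every group covers the same state
#' vocabulary.
#'
#' @param cells Cell table the labeling was computed on (rows aligned with
#'   \code{labeling}; dying cells must have been excluded consistently).
#' @param labeling A \linkS4class{StateLabeling}, or a character vector of
#'   per-cell labels.
#' @param groupKeys Column names of \code{cells} to group by; NULL pools all
#'   cells into one group.
#' @param states State vocabulary; defaults to the labels present.
#' @return data.frame: grouping keys, \code{state}, \code{Pi} (proportion),
#'   \code{n} (group total cell count).
#' @export
stateFrequencies <- function(cells, labeling, groupKeys = NULL, states = NULL) {
  labels <- if (is(labeling, "StateLabeling")) labeling@labels else labeling
  if (length(labels) != nrow(cells))
    stop("labeling length does not match the cell table")
  if (is.null(states)) states <- sort(unique(labels))
  grp <- if (is.null(groupKeys)) rep("all", length(labels))
         else interaction(cells[groupKeys], drop = TRUE, sep = "\r")
  out <- list()
  for (g in levels(factor(grp))) {
    idx <- grp == g
    n <- sum(idx)
    if (n == 0L) { warning("empty group dropped: ", g); next }
    tab <- table(factor(labels[idx], levels = states))
    row <- data.frame(state = states, Pi = as.numeric(tab) / n, n = n)
    if (!is.null(groupKeys)) {
      keyVals <- strsplit(g, "\r", fixed = TRUE)[[1]]
      for (i in seq_along(groupKeys)) row[[groupKeys[i]]] <- keyVals[i]
      row <- row[, c(groupKeys, "state", "Pi", "n")]
    }
    out[[g]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Marker Z-score change of treated wells against control wells
#'
#' Z = (treated mean-cell MFI - mean of per-well control means) / SD of
#' per-well control means. Control wells are weighted equally regardless of
#' their cell counts.
#'
#' @param cells Cell table.
#' @param treatedWells,controlWells Well ids in \code{cells$well_id}.
#' @param marker One of "K19", "K14", "VIM".
#' @param excludeDying Drop cells flagged \code{dying}.
#' @return Z-score (dimensionless scalar).
#' @export
markerZscoreChange <- function(cells, treatedWells, controlWells, marker,
                               excludeDying = TRUE) {
  col <- .checkMarkers(cells, marker)
  cells <- .gateable(cells, excludeDying)
  ctrlMeans <- vapply(controlWells, function(w) {
    x <- cells[[col]][cells$well_id == w]
    if (!length(x)) NA_real_ else mean(x)
  }, numeric(1))
  ctrlMeans <- ctrlMeans[!is.na(ctrlMeans)]
  if (length(ctrlMeans) < 2L)
    stop("need >= 2 non-empty control wells to define spread")
  s <- sd(ctrlMeans)
  if (s == 0) stop("zero control-well spread: Z undefined")
  treated <- cells[[col]][cells$well_id %in% treatedWells]
  if (!length(treated)) stop("no cells in the treated wells")
  (mean(treated) - mean(ctrlMeans)) / s
}

#' Fraction of flagged cells per state
#'
#' For a binary event flag (EdU incorporation, YO-PRO-1 dying, ...), reports
#' the flagged fraction within each state and overall.
#'
#' @param labeling A \linkS4class{StateLabeling} or character label vector.
#' @param flag 0/1 (or logical) vector aligned with the labels.
#' @param states State vocabulary; states with no cells get NA.
#' @return data.frame: \code{state} (including \code{"overall"}),
#'   \code{fraction}, \code{n}.
#' @export
flagFractionByState <- function(labeling, flag, states = NULL) {
  labels <- if (is(labeling, "StateLabeling")) labeling@labels else labeling
  flag <- as.integer(flag)
  if (length(flag) != length(labels))
    stop("flag length does not match the labeling")
  if (!all(flag %in% c(0L, 1L))) stop("flag must be binary 0/1")
  if (is.null(states)) states <- sort(unique(labels))
  frac <- vapply(states, function(s) {
    idx <- labels == s
    if (!any(idx)) NA_real_ else mean(flag[idx])
  }, numeric(1))
  n <- vapply(states, function(s) sum(labels == s), numeric(1))
  rbind(data.frame(state = states, fraction = frac, n = n),
        data.frame(state = "overall",
                   fraction = if (length(flag)) mean(flag) else NA_real_,
                   n = length(flag)))
}
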