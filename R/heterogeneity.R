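#' Shannon diversity index of a cell-state frequency distribution
#'
#' H' = -sum_i Pi * log(Pi) over states with Pi > 0. The default log base is
#' natural (nats); base 2 reports bits. S counts the states actually present
#' (Pi > 0). H' is 0 iff a single state has Pi = 1 and is maximal, log(S),
#' at the uniform distribution.
#'
#' @param Pi Numeric vector of state proportions (nonnegative, summing to 1
#'   within 1e-9).
#' @param base Log base: \code{exp(1)} (default, nats) or \code{2} (bits).
#' @return List of class \code{DiversityResult}: \code{H}, \code{S},
#'   \code{base}.
#' @examples
#' shannonIndex(rep(1/8, 8))          # ln 8
#' shannonIndex(rep(1/8, 8), base = 2) # 3 bits
#' @export
shannonIndex <- function(Pi, base = exp(1)) {
  if (any(Pi < 0)) stop("proportions must be nonnegative")
  if (abs(sum(Pi) - 1) > 1e-9) stop("proportions must sum to 1 (tol 1e-9)")
  p <- Pi[Pi > 0]
  structure(list(H = -sum(p * log(p, base = base)), S = length(p),
                 base = base),
            class = "DiversityResult")
}

#' @export
print.DiversityResult <- function(x, ...) {
  unit <- if (isTRUE(all.equal(x$base, 2))) "bits"
          else if (isTRUE(all.equal(x$base, exp(1)))) "nats"
          else sprintf("log-base-%g units", x$base)
  cat(sprintf("Shannon diversity H' = %.4f %s over S = %d states\n",
              x$H, unit, x$S))
  invisible(x)
}

#' Shannon diversity per group of a state-frequency table
#'
#' @param freqs data.frame from \code{\link{stateFrequencies}} (columns
#'   \code{state}, \code{Pi}, plus grouping keys).
#' @param groupKeys Grouping key columns present in \code{freqs}; NULL treats
#'   the table as one group.
#' @param base Log base (see \code{\link{shannonIndex}}).
#' @return data.frame: grouping keys, \code{H}, \code{S}, \code{base}.
#' @export
diversityTable <- function(freqs, groupKeys = NULL, base = exp(1)) {
  grp <- if (is.null(groupKeys)) rep("all", nrow(freqs))
         else interaction(freqs[groupKeys], drop = TRUE, sep = "\r")
  out <- lapply(levels(factor(grp)), function(g) {
    sub <- freqs[grp == g, , drop = FALSE]
    d <- shannonIndex(sub$Pi, base = base)
    row <- data.frame(H = d$H, S = d$S, base = base)
    if (!is.null(groupKeys)) {
      keyVals <- strsplit(g, "\r", fixed = TRUE)[[1]]
      for (i in seq_along(groupKeys)) row[[groupKeys[i]]] <- keyVals[i]
      row <- row[, c(groupKeys, "H", "S", "base")]
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Per-gene Z-scores across samples (population SD, denominator n).
.geneZ <- function(expr) {
  if (ncol(expr) < 2L) stop("need >= 2 samples to Z-score across samples")
  mu <- rowMeans(expr)
  sdev <- sqrt(rowMeans((expr - mu)^2))
  sdev[sdev == 0] <- NA_real_
  (expr - mu) / sdev
}

.checkGenes <- function(expr, genesets) {
  miss <- setdiff(unlist(genesets), rownames(expr))
  if (length(miss))
    stop("geneset genes missing from the expression matrix: ",
         paste(miss, collapse = ", "))
}

#' Cumulative geneset Z-score per sample
#'
#' Genes are Z-scored across samples (population SD); a sample's cumulative
#' score is the sum of its Z-scores over the union of the lineage genesets
#' (75 genes for the default luminal/myoepithelial/EMT collection). Samples
#' co-expressing all three lineage programs score highest.
#'
#' @param expr Genes x samples matrix with gene rownames.
#' @param genesets Named list of gene vectors (disjoint).
#' @return Named numeric, one cumulative Z per sample.
#' @export
cumulativeGenesetZscore <- function(expr, genesets) {
  .checkGenes(expr, genesets)
  z <- .geneZ(expr)[unlist(genesets), , drop = FALSE]
  colSums(z, na.rm = TRUE)
}

#' Between-geneset variance per sample
#'
#' For each sample, the mean per-gene Z-score within each geneset is
#' computed; the statistic is the sample variance (denominator n - 1, over
#' exactly the 3 geneset means). Low variance with high cumulative Z marks
#' samples that co-express all lineage programs (molecularly heterogeneous,
#' basal-like behaviour); high variance marks lineage-committed samples.
#'
#' @inheritParams cumulativeGenesetZscore
#' @return Named numeric, one variance per sample.
#' @export
betweenGenesetVariance <- function(expr, genesets) {
  .checkGenes(expr, genesets)
  z <- .geneZ(expr)
  setMeans <- vapply(genesets, function(g)
    colMeans(z[g, , drop = FALSE], na.rm = TRUE),
    numeric(ncol(expr)))
  apply(matrix(setMeans, ncol = length(genesets)), 1L, var)
}

#' Read a GMT geneset file
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   member genes).
#' @return Named list of gene vectors.
#' @export
readGMT <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a GMT geneset file
#'
#' @param genesets Named list of gene vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description column.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(genesets, path, descriptions = names(genesets)) {
  lines <- vapply(seq_along(genesets), function(i)
    paste(c(names(genesets)[i], descriptions[i], genesets[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
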