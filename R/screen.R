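# Drug-screen analytics: percent-of-control viability, log-logistic
# dose-response characterization (Emax / projected Einf), phenotype response
# profiles, k-means response groups, and Chou-Talalay combination indices
# from fixed-ratio dose-escalation series.

#' Percent-of-control viability
#'
#' Scales a well signal between the positive control (cell-free media, 0\%)
#' and the negative control (vehicle, 100\%):
#' \code{100 * (signal - pos) / (neg - pos)}. Affine-invariant: adding a
#' constant to all signals and controls leaves it unchanged.
#'
#' @param signal Well signal(s).
#' @param negControlMean Mean vehicle-control signal (must exceed
#'   \code{posControlMean}).
#' @param posControlMean Mean cell-free control signal.
#' @return Percent of control (may exceed 100 or fall below 0).
#' @export
percentOfControl <- function(signal, negControlMean, posControlMean = 0) {
  if (negControlMean <= posControlMean)
    stop("negative-control mean must exceed positive-control mean")
  100 * (signal - posControlMean) / (negControlMean - posControlMean)
}

#' Fit a log-logistic dose-response curve with the top pinned at 100
#'
#' Least-squares fit of
#' \code{y = bottom + (100 - bottom) / (1 + (D / EC50)^slope)} with bottom
#' (the projected maximal-inhibition asymptote, Einf, reported as \% control
#' and allowed to be negative), EC50 and slope free. Emax is the minimum
#' observed percent-of-control, always attained by a data point. Fitting
#' uses Levenberg-Marquardt with a coarse grid start; non-convergence is
#' flagged and Emax still reported.
#'
#' @param doses Positive dose vector (>= 4 points).
#' @param pctControl Percent-of-control responses.
#' @return List of class \code{DoseResponseFit}: \code{EC50}, \code{slope},
#'   \code{top} (100), \code{Einf}, \code{Emax}, \code{rss},
#'   \code{converged}.
#' @export
fitDoseResponse <- function(doses, pctControl) {
  if (length(doses) < 4L) stop("need >= 4 dose points")
  if (any(doses <= 0)) stop("doses must be positive")
  if (length(doses) != length(pctControl)) stop("length mismatch")
  emax <- min(pctControl)
  mkFit <- function(b, e, s, rss, conv) structure(
    list(EC50 = e, slope = s, top = 100, Einf = b, Emax = emax,
         rss = rss, converged = conv), class = "DoseResponseFit")
  if (sd(pctControl) < 1e-12)   # flat response: curve degenerates
    return(mkFit(mean(pctControl), median(doses), 1, 0, TRUE))

  pred <- function(b, e, s) b + (100 - b) / (1 + (doses / e)^s)
  grid <- expand.grid(b = c(min(pctControl), 0, 50),
                      e = quantile(doses, c(0.1, 0.5, 0.9)),
                      s = c(0.5, 1, 2))
  rssOf <- function(p) sum((pctControl - pred(p[1], p[2], p[3]))^2)
  starts <- lapply(grid[order(apply(grid, 1, rssOf))[1], ], unname)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      pctControl ~ b + (100 - b) / (1 + (doses / e)^s),
      start = list(b = starts$b, e = starts$e, s = starts$s),
      lower = c(b = -Inf, e = 1e-12, s = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    return(mkFit(unname(cf["b"]), unname(cf["e"]), unname(cf["s"]),
                 sum(residuals(fit)^2), TRUE))
  }
  # fallback: direct simplex on the same loss
  op <- optim(unlist(starts), function(p) rssOf(c(p[1], max(p[2], 1e-12),
                                                  max(p[3], 1e-6))))
  mkFit(op$par[1], max(op$par[2], 1e-12), max(op$par[3], 1e-6),
        op$value, FALSE)
}

#' @export
print.DoseResponseFit <- function(x, ...) {
  cat(sprintf("Log-logistic fit (top = 100): EC50 = %.4g, slope = %.3g\n",
              x$EC50, x$slope))
  cat(sprintf("  Emax = %.2f%%, projected Einf = %.2f%%, RSS = %.4g%s\n",
              x$Emax, x$Einf, x$rss,
              if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' Fit the median-effect (Chou-Talalay) model
#'
#' Linearizes \code{fa/fu = (D/Dm)^m} as a regression of
#' \code{log(fa/(1-fa))} on \code{log(D)}; \code{m} is the slope and
#' \code{Dm} the dose of median effect (fa = 0.5). Points are clamped to
#' [clamp, 1-clamp]; points at or below fa = 0 (viability >= 100\%) are
#' dropped with a warning.
#'
#' @param doses Positive dose vector.
#' @param fa Affected fractions (1 - pctControl/100).
#' @param clamp Clamping bound for fa near 0/1 (default 0.005).
#' @return List of class \code{MedianEffectFit}: \code{m}, \code{Dm},
#'   \code{r2}, \code{n}, \code{valid}.
#' @export
fitMedianEffect <- function(doses, fa, clamp = 0.005) {
  if (any(doses <= 0)) stop("doses must be positive")
  keep <- !is.na(fa) & fa > 0
  if (any(!keep))
    warning(sprintf("%d point(s) with fa <= 0 dropped", sum(!keep)))
  doses <- doses[keep]; fa <- pmin(pmax(fa[keep], clamp), 1 - clamp)
  if (length(doses) < 2L)
    return(structure(list(m = NA_real_, Dm = NA_real_, r2 = NA_real_,
                          n = length(doses), valid = FALSE),
                     class = "MedianEffectFit"))
  y <- log(fa / (1 - fa)); x <- log(doses)
  f <- lm(y ~ x)
  m <- unname(coef(f)[2]); b <- unname(coef(f)[1])
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(residuals(f)^2) / tss else 1
  structure(list(m = m, Dm = exp(-b / m), r2 = r2, n = length(doses),
                 valid = is.finite(m) && m > 0),
            class = "MedianEffectFit")
}

#' @export
print.MedianEffectFit <- function(x, ...) {
  if (x$valid)
    cat(sprintf("Median-effect fit: m = %.4g, Dm = %.4g (R2 = %.4f, n = %d)\n",
                x$m, x$Dm, x$r2, x$n))
  else cat("Median-effect fit: invalid (insufficient usable points)\n")
  invisible(x)
}

#' Iso-effective dose at effect level x
#'
#' \code{Dx = Dm * (x / (1 - x))^(1/m)} from a median-effect fit.
#'
#' @param fit A \code{MedianEffectFit}.
#' @param x Effect level in (0, 1).
#' @return Dose producing affected fraction x.
#' @export
isoEffectiveDose <- function(fit, x) {
  stopifnot(inherits(fit, "MedianEffectFit"))
  if (!fit$valid) return(NA_real_)
  fit$Dm * (x / (1 - x))^(1 / fit$m)
}

#' Chou-Talalay combination index at fixed effect levels
#'
#' For a constant-ratio combination dosed by total concentration, the CI at
#' effect level x is \code{d1/Dx1 + d2/Dx2}, where \code{Dx_j} are the
#' single-agent iso-effective doses, \code{Dx_combo} the combination's
#' iso-effective total dose, and \code{d1 = rho_A * Dx_combo},
#' \code{d2 = rho_B * Dx_combo} its components. CI < 1 indicates synergy,
#' 1 additivity, > 1 antagonism. Reported at the 75\% and 90\% inhibitory
#' levels (CI75, CI90) by default.
#'
#' @param fitA,fitB,fitCombo \code{MedianEffectFit}s for the single agents
#'   and the fixed-ratio mixture (dosed by total concentration).
#' @param ratio Numeric c(rhoA, rhoB) dose fractions of A and B in the
#'   mixture (default equimolar 1:1); normalized to sum to 1.
#' @param effectLevels Effect levels x (default c(0.75, 0.90)).
#' @return data.frame of class \code{CombinationIndexResult}: \code{level},
#'   \code{CI}, \code{d1}, \code{d2}, \code{Dx1}, \code{Dx2},
#'   \code{DxCombo}.
#' @export
combinationIndex <- function(fitA, fitB, fitCombo, ratio = c(1, 1),
                             effectLevels = c(0.75, 0.90)) {
  for (f in list(fitA, fitB, fitCombo))
    if (!inherits(f, "MedianEffectFit") || !f$valid)
      stop("all three median-effect fits must be valid")
  if (any(effectLevels <= 0 | effectLevels >= 1))
    stop("effect levels must lie in (0, 1)")
  rho <- ratio / sum(ratio)
  rows <- lapply(effectLevels, function(x) {
    DxA <- isoEffectiveDose(fitA, x)
    DxB <- isoEffectiveDose(fitB, x)
    DxC <- isoEffectiveDose(fitCombo, x)
    d1 <- rho[1] * DxC; d2 <- rho[2] * DxC
    data.frame(level = x, CI = d1 / DxA + d2 / DxB, d1 = d1, d2 = d2,
               Dx1 = DxA, Dx2 = DxB, DxCombo = DxC)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("CombinationIndexResult", "data.frame")
  out
}

#' Phenotype response profile of each drug
#'
#' Per drug and dose: the change in each marker's mean-cell MFI against the
#' DMSO control wells as a Z-score (\code{\link{markerZscoreChange}}), and
#' the percent-of-control proliferation signal. The profile vector used for
#' clustering is the marker-by-dose Z-score block.
#'
#' @param screenTable data.frame with columns \code{drug}, \code{dose},
#'   \code{well_id}, \code{signal} (viability), and per-well mean-cell MFI
#'   columns \code{k19_mfi}, \code{k14_mfi}, \code{vim_mfi}.
#' @param controlWells Well ids of the DMSO wells on the same plate (>= 2).
#' @param posControlMean Cell-free control signal (default 0).
#' @return data.frame: \code{drug}, \code{dose}, \code{dZ_K19},
#'   \code{dZ_VIM}, \code{dZ_K14}, \code{pctControl}.
#' @export
responseProfile <- function(screenTable, controlWells, posControlMean = 0) {
  need <- c("drug", "dose", "well_id", "signal",
            "k19_mfi", "k14_mfi", "vim_mfi")
  miss <- setdiff(need, names(screenTable))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  ctrl <- screenTable[screenTable$well_id %in% controlWells, , drop = FALSE]
  if (length(unique(ctrl$well_id)) < 2L)
    stop("need >= 2 control wells")
  negMean <- mean(tapply(ctrl$signal, ctrl$well_id, mean))
  zOf <- function(vals, col) {
    cm <- tapply(ctrl[[col]], ctrl$well_id, mean)
    s <- sd(cm)
    if (s == 0) stop("zero control-well spread for ", col)
    (mean(vals) - mean(cm)) / s
  }
  drugs <- screenTable[!screenTable$well_id %in% controlWells, , drop = FALSE]
  out <- list(); k <- 0L
  for (dr in unique(drugs$drug)) {
    for (dose in sort(unique(drugs$dose[drugs$drug == dr]))) {
      dd <- drugs[drugs$drug == dr & drugs$dose == dose, , drop = FALSE]
      k <- k + 1L
      out[[k]] <- data.frame(
        drug = dr, dose = dose,
        dZ_K19 = zOf(dd$k19_mfi, "k19_mfi"),
        dZ_VIM = zOf(dd$vim_mfi, "vim_mfi"),
        dZ_K14 = zOf(dd$k14_mfi, "k14_mfi"),
        pctControl = mean(percentOfControl(dd$signal, negMean,
                                           posControlMean)))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# k-means++ seeding (squared-distance-proportional center choice).
.kmeansPP <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k)[-1]) {
    pick <- if (all(d2 == 0)) sample.int(n, 1L)
            else sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Cluster drug response profiles by k-means
#'
#' K-means on the marker Z-score-change vectors with k-means++
#' initialization, best of \code{nRestarts} restarts by total within-cluster
#' sum of squares; deterministic given the seed. Default k = 6 response
#' groups. Profiles with missing entries are excluded.
#'
#' @param profiles Numeric matrix, one row per drug (complete rows only are
#'   used).
#' @param k Number of clusters (>= 2, default 6).
#' @param seed Integer seed.
#' @param nRestarts Number of k-means++ restarts (default 10).
#' @return List: \code{cluster} (named labels), \code{centers},
#'   \code{totWithinSS}, \code{excluded} (rownames of incomplete profiles).
#' @export
clusterResponseProfiles <- function(profiles, k = 6, seed = 1L,
                                    nRestarts = 10L) {
  profiles <- as.matrix(profiles)
  if (k < 2L) stop("k must be >= 2")
  complete <- complete.cases(profiles)
  x <- profiles[complete, , drop = FALSE]
  if (nrow(x) < k) stop("fewer complete profiles than clusters")
  withSeed(seed, {
    best <- NULL
    for (r in seq_len(nRestarts)) {
      km <- tryCatch(
        kmeans(x, centers = .kmeansPP(x, k), iter.max = 100L),
        error = function(e) NULL)
      if (!is.null(km) &&
          (is.null(best) || km$tot.withinss < best$tot.withinss))
        best <- km
    }
    if (is.null(best)) stop("k-means failed on every restart")
    list(cluster = setNames(best$cluster, rownames(x)),
         centers = best$centers, totWithinSS = best$tot.withinss,
         excluded = rownames(profiles)[!complete])
  })
}

#' Generate a synthetic well-level screen table
#'
#' Produces per-well viability signals and mean-cell marker MFIs for a set
#' of drugs with specified top-dose effects, plus DMSO control wells, for
#' exercising \code{\link{responseProfile}}. Marker effects scale linearly
#' with dose rank; viability follows a log-logistic decline to the drug's
#' floor.
#'
#' @param drugEffects data.frame: \code{drug}, \code{k19}, \code{k14},
#'   \code{vim} (multiplicative top-dose MFI fold effects), \code{floor}
#'   (viability floor, \% control).
#' @param doses Dose grid shared by all drugs.
#' @param nControl Number of DMSO wells.
#' @param baseline Named numeric baseline MFIs c(k19=, k14=, vim=).
#' @param cv Well-to-well noise CV.
#' @param seed Integer seed.
#' @return data.frame usable as \code{screenTable} in
#'   \code{\link{responseProfile}}.
#' @export
generateScreenTable <- function(drugEffects,
                                doses = 10^seq(-3, 3, by = 1),
                                nControl = 8L,
                                baseline = c(k19 = 300, k14 = 150, vim = 100),
                                cv = 0.03, seed = 1L) {
  withSeed(seed, {
    noise <- function(n) rlnorm(n, 0, cv)
    rows <- list(); k <- 0L
    for (i in seq_len(nControl)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        drug = "DMSO", dose = 0, well_id = sprintf("ctrl_%02d", i),
        signal = 1000 * noise(1), k19_mfi = baseline[["k19"]] * noise(1),
        k14_mfi = baseline[["k14"]] * noise(1),
        vim_mfi = baseline[["vim"]] * noise(1))
    }
    for (i in seq_len(nrow(drugEffects))) {
      de <- drugEffects[i, ]
      for (j in seq_along(doses)) {
        s <- j / length(doses)   # dose-rank scaling of the phenotype effect
        viability <- de$floor + (100 - de$floor) /
          (1 + (doses[j] / median(doses))^1)
        k <- k + 1L
        rows[[k]] <- data.frame(
          drug = de$drug, dose = doses[j],
          well_id = sprintf("%s_d%d", de$drug, j),
          signal = 10 * viability * noise(1),
          k19_mfi = baseline[["k19"]] * (1 + (de$k19 - 1) * s) * noise(1),
          k14_mfi = baseline[["k14"]] * (1 + (de$k14 - 1) * s) * noise(1),
          vim_mfi = baseline[["vim"]] * (1 + (de$vim - 1) * s) * noise(1))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
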