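# Shared fixture builders. Everything is generated in code at test time.

# CompartmentTrajectories holding exact deterministic trajectories from
# `truth`, one well per starting vector in x0List.
deterministicTraj <- function(truth, x0List, nSteps = 6, arm = "treated") {
  d <- do.call(rbind, lapply(seq_along(x0List), function(i) {
    s <- simulateDeterministic(truth, x0List[[i]], nSteps)
    data.frame(well_id = sprintf("w%02d", i), arm = arm,
               timepoint_h = 12 * (0:nSteps),
               nHi = s[, "nHi"], nLo = s[, "nLo"], nDead = s[, "nDead"],
               observed = TRUE, floored = FALSE)
  }))
  new("CompartmentTrajectories", data = d, hypothesis = "exact")
}

# Mask the given record indices (never t = 0) of a trajectory object.
maskTraj <- function(traj, idx) {
  d <- traj@data
  stopifnot(all(d$timepoint_h[idx] > 0))
  d$observed[idx] <- FALSE
  d[idx, c("nHi", "nLo", "nDead")] <- NA_real_
  new("CompartmentTrajectories", data = d, hypothesis = traj@hypothesis)
}

# A random cell table with independent lognormal marker MFIs (no state
# structure) for gating property checks.
randomCellTable <- function(n, seed) {
  withr::with_seed(seed, data.frame(
    cell_id = seq_len(n),
    well_id = sample(c("w1", "w2", "w3"), n, replace = TRUE),
    arm = sample(c("DMSO", "drug"), n, replace = TRUE),
    timepoint_h = 0,
    k19_mfi = rlnorm(n, log(150), 0.8),
    k14_mfi = rlnorm(n, log(150), 0.8),
    vim_mfi = rlnorm(n, log(150), 0.8),
    edu_pos = rbinom(n, 1, 0.3), dying = 0L,
    true_state = NA_character_))
}

# Ground-truth config for the Darwinian-favoring (converse) design:
# no transitions, death only from the K14lo state, strong cytostasis.
converseConfig <- function(seed) {
  groundTruthConfig(
    arms = list(
      DMSO = rateParameters(aHi = 0.35, aLo = 0.35, dHi = 0.01, dLo = 0.01,
                            kHL = 0.022, kLH = 0.008),
      treated = rateParameters(aHi = 0.02, aLo = 0.02, dHi = 0, dLo = 0.33,
                               kHL = 0, kLH = 0)),
    seed = seed)
}

# Independent direct constrained least-squares oracle for complete data:
# solves the reduced normal equations after eliminating the hypothesis
# equalities (valid when no inequality constraint is active at the optimum).
directFitOracle <- function(traj, hypothesis, arm, lambda = 1e-3) {
  d <- traj@data
  d <- d[d$arm == arm, ]
  d <- d[order(d$well_id, d$timepoint_h), ]
  stopifnot(all(d$observed))
  basis <- list(
    aHi = rbind(c(1, 0, 0), 0, 0), aLo = rbind(0, c(0, 1, 0), 0),
    dHi = rbind(c(-1, 0, 0), 0, c(1, 0, 0)),
    dLo = rbind(0, c(0, -1, 0), c(0, 1, 0)),
    kHL = rbind(c(-1, 0, 0), c(1, 0, 0), 0),
    kLH = rbind(c(0, 1, 0), c(0, -1, 0), 0))
  M <- NULL; z <- NULL
  for (w in unique(d$well_id)) {
    Y <- as.matrix(d[d$well_id == w, c("nHi", "nLo", "nDead")])
    for (t in seq_len(nrow(Y) - 1)) {
      M <- rbind(M, sapply(basis, function(B) B %*% Y[t, ]))
      z <- c(z, Y[t + 1, ] - Y[t, ])
    }
  }
  # equality elimination mirrors the hypothesis but is assembled
  # independently here
  nm <- c("aHi", "aLo", "dHi", "dLo", "kHL", "kLH")
  cls <- setNames(nm, nm)
  for (g in hypothesis@ties) cls[g] <- g[1]
  fixed <- names(hypothesis@fixes)
  fixed <- nm[cls %in% cls[fixed]]
  free <- unique(cls[!(nm %in% fixed)])
  S <- matrix(0, 6, length(free), dimnames = list(nm, free))
  for (p in nm) if (!(p %in% fixed)) S[p, cls[[p]]] <- 1
  s0 <- setNames(numeric(6), nm)
  s0[fixed] <- hypothesis@fixes[cls[fixed]]
  Q <- crossprod(M) + diag(lambda, 6)
  phi <- solve(t(S) %*% Q %*% S, t(S) %*% (crossprod(M, z) - Q %*% s0))
  setNames(drop(S %*% phi + s0), nm)
}

# Adjusted Rand index (used where mclust is unavailable it is skipped by
# loading check in the calling test).
ariOf <- function(a, b) mclust::adjustedRandIndex(a, b)
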