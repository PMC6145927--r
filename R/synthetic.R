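#' Default state-conditional marker intensity model
#'
#' Each (state, marker) pair gets a right-skewed positive distribution,
#' parametrized as \code{c(location, spread)}: draws are
#' \code{location * rlnorm(n, 0, spread)}, so \code{location} is the median
#' MFI (arbitrary units, must be > 0) and \code{spread} the log-scale SD
#' (>= 0; 0 collapses to a point mass). The defaults emulate a basal-like
#' line in which K14hi cells are K19hi/K14hi with low VIM and K14lo cells
#' are K19hi with moderate VIM; the two K14 distributions are well separated
#' (4x the location at a quarter of the spread overlap region).
#'
#' @return Nested list: state -> marker -> c(location, spread).
#' @export
defaultIntensityModel <- function() {
  list(
    K14hi = list(K19 = c(300, 0.25), K14 = c(400, 0.25), VIM = c(60, 0.30)),
    K14lo = list(K19 = c(300, 0.25), K14 = c(100, 0.25), VIM = c(120, 0.30))
  )
}

#' Ground-truth configuration for a synthetic time-course experiment
#'
#' Encodes the experimental design being emulated: 15 replicate wells per arm
#' sampled every 12 h over a 72 h horizon, with a vehicle (DMSO) arm and one
#' or more treated arms, per-cell marker intensities drawn from
#' state-conditional distributions, multiplicative measurement noise on the
#' reported counts, and a fraction of illegible (masked) well x time records.
#'
#' The default treated arm is "transition-like": near-zero proliferation
#' (strong cytostasis), equal per-capita death in both states, and a strong
#' net K14lo -> K14hi transition flux that carries the K14hi frequency from
#' ~27\% to ~80\% over six steps. The default control arm proliferates and
#' sits near its transition equilibrium (~27\% K14hi).
#'
#' @param arms Named list of \linkS4class{RateParameters}, one per arm.
#' @param controlArm Name of the vehicle arm within \code{arms}.
#' @param initCounts Named numeric c(hi=, lo=): cells per well at time 0.
#' @param nWells Replicate wells per arm.
#' @param timepoints Hours, strictly increasing, starting at 0.
#' @param intensityModel See \code{\link{defaultIntensityModel}}.
#' @param noiseCV Multiplicative coefficient of variation on reported counts.
#' @param missingFraction Proportion of t > 0 records masked as illegible.
#' @param seed Integer master seed.
#' @return A validated list of class \code{GroundTruthConfig}.
#' @export
groundTruthConfig <- function(
    arms = list(
      DMSO = rateParameters(aHi = 0.35, aLo = 0.35, dHi = 0.01, dLo = 0.01,
                            kHL = 0.022, kLH = 0.008),
      treated = rateParameters(aHi = 0.02, aLo = 0.02, dHi = 0.02, dLo = 0.02,
                               kHL = 0.005, kLH = 0.2)),
    controlArm = "DMSO",
    initCounts = c(hi = 540, lo = 1460),
    nWells = 15,
    timepoints = seq(0, 72, by = 12),
    intensityModel = defaultIntensityModel(),
    noiseCV = 0.1,
    missingFraction = 0.2,
    seed = 1L) {
  if (is.null(names(arms)) || !all(nzchar(names(arms))))
    stop("arms must be a named list of RateParameters")
  if (!controlArm %in% names(arms))
    stop("controlArm must name an element of arms")
  for (p in arms) stopifnot(is(p, "RateParameters"))
  if (length(timepoints) < 2L || timepoints[1] != 0 ||
      is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing and start at 0")
  if (any(initCounts < 0)) stop("initial counts must be nonnegative")
  assertScalarProb(missingFraction, "missingFraction", openTop = TRUE)
  if (noiseCV < 0) stop("noiseCV must be nonnegative")
  structure(list(arms = arms, controlArm = controlArm,
                 initCounts = initCounts, nWells = as.integer(nWells),
                 timepoints = timepoints, intensityModel = intensityModel,
                 noiseCV = noiseCV, missingFraction = missingFraction,
                 seed = as.integer(seed)),
            class = "GroundTruthConfig")
}

#' Stochastic birth/death/transition trajectory of one well
#'
#' Simulates the agent-level counterpart of the LTI model on
#' (K14hi live, K14lo live, dead). At each step every live cell independently
#' (i) divides with its state's division probability (the daughter is
#' credited to the state of origin and enters the population at the next
#' step), and (ii) draws one fate from \{die, switch state, persist\}. The
#' dead compartment is cumulative; deaths are also tracked by state of origin
#' so that "measured" counts (live + dead-in-place) can be reconstructed.
#' With this scheme the ensemble mean over trajectories equals the
#' deterministic propagation \code{x(t+1) = A(theta) x(t)} exactly.
#'
#' @param params \linkS4class{RateParameters}; death + transition-out
#'   probability must be <= 1 per state.
#' @param init Named numeric c(hi=, lo=): initial live cells.
#' @param nSteps Number of steps to simulate.
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @return List with \code{counts} (matrix, (nSteps+1) x 4:
#'   \code{nHi}, \code{nLo}, \code{nDeadHi}, \code{nDeadLo}) and
#'   \code{events} (data.frame: step, state, divisions, deaths, transitions).
#' @export
simulatePopulation <- function(params, init, nSteps, seed) {
  stopifnot(is(params, "RateParameters"))
  r <- params@rates
  if (r["dHi"] + r["kHL"] > 1)
    stop("probability budget exceeded for K14hi: dHi + kHL > 1")
  if (r["dLo"] + r["kLH"] > 1)
    stop("probability budget exceeded for K14lo: dLo + kLH > 1")
  init <- round(init)
  if (any(init < 0)) stop("initial counts must be nonnegative")
  nSteps <- as.integer(nSteps)

  withSeed(seed, {
    counts <- matrix(0, nSteps + 1L, 4L,
                     dimnames = list(NULL, c("nHi", "nLo", "nDeadHi", "nDeadLo")))
    counts[1L, ] <- c(init[["hi"]], init[["lo"]], 0, 0)
    ev <- vector("list", nSteps)
    for (s in seq_len(nSteps)) {
      hi <- counts[s, "nHi"]; lo <- counts[s, "nLo"]
      divHi <- rbinom(1L, hi, r["aHi"])
      divLo <- rbinom(1L, lo, r["aLo"])
      fateHi <- drop(rmultinom(1L, hi, c(r["dHi"], r["kHL"],
                                         1 - r["dHi"] - r["kHL"])))
      fateLo <- drop(rmultinom(1L, lo, c(r["dLo"], r["kLH"],
                                         1 - r["dLo"] - r["kLH"])))
      counts[s + 1L, "nHi"] <- fateHi[3L] + fateLo[2L] + divHi
      counts[s + 1L, "nLo"] <- fateLo[3L] + fateHi[2L] + divLo
      counts[s + 1L, "nDeadHi"] <- counts[s, "nDeadHi"] + fateHi[1L]
      counts[s + 1L, "nDeadLo"] <- counts[s, "nDeadLo"] + fateLo[1L]
      ev[[s]] <- data.frame(step = s, state = c("K14hi", "K14lo"),
                            divisions = c(divHi, divLo),
                            deaths = c(fateHi[1L], fateLo[1L]),
                            transitions = c(fateHi[2L], fateLo[2L]))
    }
    list(counts = counts, events = do.call(rbind, ev))
  })
}

#' Generate a per-cell marker-intensity table
#'
#' One row per cell; marker intensities are drawn from the state-conditional
#' distributions of \code{intensityModel}; the generating state is retained
#' as a hidden ground-truth column (\code{true_state}).
#'
#' @param stateCounts data.frame with columns \code{well_id}, \code{arm},
#'   \code{timepoint_h}, \code{state}, \code{count}.
#' @param intensityModel Nested list state -> marker -> c(location, spread);
#'   markers must include K19, K14, VIM.
#' @param eduProb,dyingProb Probability that a cell is EdU-positive / dying;
#'   either a scalar or a named vector by state.
#' @param seed Integer seed.
#' @return data.frame with columns \code{cell_id}, \code{well_id},
#'   \code{arm}, \code{timepoint_h}, \code{k19_mfi}, \code{k14_mfi},
#'   \code{vim_mfi}, \code{edu_pos}, \code{dying}, \code{true_state}.
#' @export
generateCellTable <- function(stateCounts, intensityModel = defaultIntensityModel(),
                              eduProb = 0, dyingProb = 0, seed = 1L) {
  stopifnot(all(c("well_id", "arm", "timepoint_h", "state", "count") %in%
                  names(stateCounts)))
  for (st in names(intensityModel)) {
    for (mk in names(intensityModel[[st]])) {
      p <- intensityModel[[st]][[mk]]
      if (p[1] <= 0 || p[2] < 0)
        stop(sprintf("intensity model for (%s, %s): location must be > 0 and spread >= 0",
                     st, mk))
    }
  }
  probFor <- function(p, st) if (length(p) > 1L) unname(p[[st]]) else unname(p)
  markerCol <- c(K19 = "k19_mfi", K14 = "k14_mfi", VIM = "vim_mfi")

  withSeed(seed, {
    rows <- vector("list", nrow(stateCounts))
    for (i in seq_len(nrow(stateCounts))) {
      n <- stateCounts$count[i]
      if (n <= 0) next
      st <- stateCounts$state[i]
      if (!st %in% names(intensityModel))
        stop(sprintf("no intensity model for state '%s'", st))
      d <- data.frame(
        well_id = stateCounts$well_id[i], arm = stateCounts$arm[i],
        timepoint_h = stateCounts$timepoint_h[i],
        k19_mfi = NA_real_, k14_mfi = NA_real_, vim_mfi = NA_real_,
        edu_pos = rbinom(n, 1L, probFor(eduProb, st)),
        dying = rbinom(n, 1L, probFor(dyingProb, st)),
        true_state = st)
      for (mk in names(markerCol)) {
        p <- intensityModel[[st]][[mk]]
        if (is.null(p)) stop(sprintf("marker %s missing from intensity model", mk))
        d[[markerCol[[mk]]]] <- p[1] * rlnorm(n, 0, p[2])
      }
      rows[[i]] <- d
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- data.frame(
      well_id = character(0), arm = character(0), timepoint_h = numeric(0),
      k19_mfi = numeric(0), k14_mfi = numeric(0), vim_mfi = numeric(0),
      edu_pos = integer(0), dying = integer(0), true_state = character(0))
    out <- cbind(cell_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
  })
}

#' Generate a full replicate-well time-course experiment
#'
#' For each arm and well a stochastic trajectory is simulated; reported per
#' (well, time) are the gated state counts with multiplicative lognormal
#' noise rounded to integers, and the death fraction. Cells that died during
#' the preceding sampling interval are still present in the imaged field and
#' are gated in the state they died from, so measured counts are live cells
#' plus the newly dead; cells dead longer than one interval have detached
#' and left both the counts and the death-fraction denominator. The death
#' fraction is therefore the currently-dying fraction (newly dead over total
#' imaged cells). A uniformly random subset of t > 0 records (the missing
#' fraction) is masked as illegible. The complete unmasked ground truth is
#' returned alongside.
#'
#' @param config A \code{\link{groundTruthConfig}}.
#' @return List with \code{timecourse} (a \linkS4class{TimeCourse}) and
#'   \code{truth} (list: \code{params}, \code{trajectories} data.frame of
#'   noiseless live/dead compartments and measured counts, \code{config}).
#' @export
generateTimecourse <- function(config = groundTruthConfig()) {
  stopifnot(inherits(config, "GroundTruthConfig"))
  nSteps <- length(config$timepoints) - 1L
  rows <- list(); truthRows <- list(); k <- 0L

  for (arm in names(config$arms)) {
    for (w in seq_len(config$nWells)) {
      k <- k + 1L
      wellId <- sprintf("%s_w%02d", arm, w)
      sim <- simulatePopulation(config$arms[[arm]], config$initCounts,
                                nSteps, childSeed(config$seed, k))
      cc <- sim$counts
      # cells that died during the preceding interval are still in the imaged
      # field (gated in their state of death); earlier dead have detached
      newDeadHi <- c(0, diff(cc[, "nDeadHi"]))
      newDeadLo <- c(0, diff(cc[, "nDeadLo"]))
      measHi <- cc[, "nHi"] + newDeadHi
      measLo <- cc[, "nLo"] + newDeadLo
      dead <- newDeadHi + newDeadLo
      noisy <- withSeed(childSeed(config$seed, k + 100000L), {
        f <- function(x) round(x * rlnorm(length(x), 0, config$noiseCV))
        list(hi = f(measHi), lo = f(measLo), dead = f(dead))
      })
      df <- pmin(pmax(noisy$dead / pmax(noisy$hi + noisy$lo, 1), 0), 1)
      rows[[k]] <- data.frame(
        well_id = wellId, arm = arm, timepoint_h = config$timepoints,
        count_k14hi = noisy$hi, count_k14lo = noisy$lo,
        death_fraction = df, observed = TRUE)
      truthRows[[k]] <- data.frame(
        well_id = wellId, arm = arm, timepoint_h = config$timepoints,
        liveHi = cc[, "nHi"], liveLo = cc[, "nLo"],
        deadHi = cc[, "nDeadHi"], deadLo = cc[, "nDeadLo"],
        measHi = measHi, measLo = measLo)
    }
  }
  tc <- do.call(rbind, rows)

  if (config$missingFraction > 0) {
    mask <- withSeed(childSeed(config$seed, 999983L),
                     runif(nrow(tc)) < config$missingFraction)
    mask[tc$timepoint_h == 0] <- FALSE
    tc$observed[mask] <- FALSE
    tc$count_k14hi[mask] <- NA_real_
    tc$count_k14lo[mask] <- NA_real_
    tc$death_fraction[mask] <- NA_real_
  }
  list(timecourse = TimeCourse(tc, controlArm = config$controlArm),
       truth = list(params = config$arms,
                    trajectories = do.call(rbind, truthRows),
                    config = config))
}

#' Generate median-effect dose/affected-fraction data
#'
#' The affected fraction follows the median-effect equation
#' \code{fa = (D/Dm)^m / (1 + (D/Dm)^m)}, optionally perturbed by
#' multiplicative lognormal noise and clamped to the open unit interval.
#'
#' @param m Median-effect slope (> 0).
#' @param Dm Median-effect dose (> 0, dose units).
#' @param doses Positive dose vector.
#' @param cv Noise coefficient of variation (0 = noiseless).
#' @param seed Integer seed (ignored when \code{cv = 0}).
#' @return data.frame with columns \code{dose}, \code{fa}.
#' @export
generateMedianEffectData <- function(m, Dm, doses, cv = 0, seed = 1L) {
  if (m <= 0 || Dm <= 0) stop("m and Dm must be positive")
  if (any(doses <= 0)) stop("doses must be positive")
  fa <- (doses / Dm)^m / (1 + (doses / Dm)^m)
  if (cv > 0)
    fa <- withSeed(seed, fa * rlnorm(length(fa), 0, cv))
  fa <- pmin(pmax(fa, 1e-9), 1 - 1e-9)
  data.frame(dose = doses, fa = fa)
}

#' Default molecular-subtype archetypes for the expression fixture
#'
#' Geneset-mean locations (Z-scale units) for four synthetic cell-line
#' archetypes mirroring a 44-line panel: basal-like lines co-express all
#' three lineage programs (high cumulative score, near-zero between-geneset
#' variance); claudin-low lines are EMT-dominant; luminal B and HER2-like
#' lines are luminal-dominant. \code{stateFreqs} gives each archetype's
#' companion cell-state frequency profile over the four prominent states,
#' used to pair molecular heterogeneity with imaging (Shannon) heterogeneity.
#'
#' @return data.frame with columns \code{name}, \code{luminal},
#'   \code{myoepithelial}, \code{emt}, \code{n}, plus a \code{stateFreqs}
#'   attribute (list of named frequency vectors).
#' @export
defaultArchetypes <- function() {
  a <- data.frame(
    name = c("basal_like", "claudin_low", "luminal_b", "her2"),
    luminal = c(2.0, -1.0, 2.5, 2.0),
    myoepithelial = c(2.0, -0.5, -1.0, -0.8),
    emt = c(2.0, 3.0, -1.5, -0.7),
    n = c(15L, 8L, 12L, 9L))
  attr(a, "stateFreqs") <- list(
    basal_like = c(K14hi = 0.30, VIMhi = 0.25, K19hi = 0.30, TripleLow = 0.15),
    claudin_low = c(K14hi = 0.01, VIMhi = 0.95, K19hi = 0.02, TripleLow = 0.02),
    luminal_b = c(K14hi = 0.02, VIMhi = 0.02, K19hi = 0.92, TripleLow = 0.04),
    her2 = c(K14hi = 0.08, VIMhi = 0.07, K19hi = 0.75, TripleLow = 0.10))
  a
}

#' Generate an expression matrix with lineage-geneset structure
#'
#' Samples are drawn around archetype-specific geneset means: every gene in a
#' geneset shares its archetype's geneset mean, plus iid Gaussian noise.
#'
#' @param archetypes data.frame as returned by \code{\link{defaultArchetypes}}.
#' @param genesets Named list of three disjoint gene vectors (luminal,
#'   myoepithelial, emt), 25 genes each by default; defaults to the shipped
#'   synthetic GMT fixture.
#' @param noise Gaussian noise SD (0 = samples equal archetype means).
#' @param seed Integer seed.
#' @return List: \code{expr} (genes x samples matrix), \code{genesets},
#'   \code{samples} (data.frame sample/archetype).
#' @export
generateExpressionFixture <- function(archetypes = defaultArchetypes(),
                                      genesets = readGMT(system.file(
                                        "extdata", "lineage_genesets_synthetic.gmt",
                                        package = "statefate")),
                                      noise = 0.5, seed = 1L) {
  if (length(genesets) != 3L)
    stop("exactly three genesets (luminal, myoepithelial, emt) expected")
  allGenes <- unlist(genesets, use.names = FALSE)
  if (anyDuplicated(allGenes))
    stop("genesets must not overlap")
  setOf <- rep(names(genesets), lengths(genesets))
  samples <- data.frame(
    sample = sprintf("%s_%02d", rep(archetypes$name, archetypes$n),
                     unlist(lapply(archetypes$n, seq_len))),
    archetype = rep(archetypes$name, archetypes$n))
  setIdx <- match(setOf, c("luminal", "myoepithelial", "emt"))
  if (anyNA(setIdx))
    stop("genesets must be named luminal, myoepithelial, emt")
  mu <- sapply(seq_len(nrow(samples)), function(j) {
    arch <- archetypes[archetypes$name == samples$archetype[j], ]
    unname(unlist(arch[c("luminal", "myoepithelial", "emt")]))[setIdx]
  })
  expr <- withSeed(seed, mu + rnorm(length(mu), 0, noise))
  dimnames(expr) <- list(allGenes, samples$sample)
  list(expr = expr, genesets = genesets, samples = samples)
}

#' Generate drug-screen response-profile archetypes
#'
#' Builds per-drug phenotype profiles (marker Z-score change vs DMSO over a
#' fixed dose grid) from six response archetypes patterned on the screen's
#' general response groups: (A) dose-dependent K14 gain, (B) K19/VIM gain
#' with K14 loss, (C) all markers up at top doses only, (D) all markers up
#' across doses, (E) minimal change, (F) variable non-dose-dependent.
#'
#' @param nPerGroup Named integer vector of drugs per archetype (A..F).
#' @param nDoses Doses per drug (profile length = nDoses x 3 markers).
#' @param noise Gaussian noise SD added to each profile entry.
#' @param seed Integer seed.
#' @return List: \code{profiles} (drugs x features matrix; features ordered
#'   marker-major K19, VIM, K14 over ascending dose), \code{groups}
#'   (character vector of generating archetypes).
#' @export
generateResponseProfiles <- function(nPerGroup = c(A = 7, B = 7, C = 7,
                                                   D = 7, E = 6, F = 6),
                                     nDoses = 7, noise = 0.3, seed = 1L) {
  s <- seq_len(nDoses) / nDoses
  base <- list(
    A = c(K19 = 0.5, VIM = -1.0, K14 = 3.0) %o% s,
    B = c(K19 = 2.5, VIM = 2.5, K14 = -1.5) %o% s,
    C = c(K19 = 2.5, VIM = 2.5, K14 = 2.5) %o% pmax(0, (s - 0.6) / 0.4),
    D = matrix(2, 3, nDoses, dimnames = list(c("K19", "VIM", "K14"), NULL)),
    E = matrix(0, 3, nDoses, dimnames = list(c("K19", "VIM", "K14"), NULL)),
    F = matrix(rep(1.8 * (-1)^seq_len(nDoses), each = 3), 3, nDoses,
               dimnames = list(c("K19", "VIM", "K14"), NULL)))
  groups <- rep(names(nPerGroup), nPerGroup)
  withSeed(seed, {
    profiles <- t(vapply(groups, function(g) {
      as.numeric(t(base[[g]])) + rnorm(3 * nDoses, 0, noise)
    }, numeric(3 * nDoses)))
    rownames(profiles) <- sprintf("drug_%s%02d", groups,
                                  unlist(lapply(nPerGroup, seq_len)))
    colnames(profiles) <- paste0(rep(c("K19", "VIM", "K14"), each = nDoses),
                                 "_d", rep(seq_len(nDoses), 3))
    list(profiles = profiles, groups = groups)
  })
}
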