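# One-config orchestration: generate -> gate -> metrics -> screen ->
# dynamics, file-based between stages (every intermediate is a CSV/JSON with
# a documented schema), with per-stage seeds and a run manifest.

#' Default pipeline run configuration
#'
#' @param outDir Output directory for all stage artifacts.
#' @param seed Master integer seed; per-stage seeds are derived from it.
#' @param stages Stages to run, in dependency order; any contiguous prefix
#'   subset of \code{c("simulate", "gate", "diversity", "screen",
#'   "dynamics")} or later stages provided earlier outputs already exist in
#'   \code{outDir}.
#' @return Config list of class \code{RunConfig}.
#' @export
defaultRunConfig <- function(outDir = tempfile("statefate_run_"), seed = 1L) {
  structure(list(
    outDir = outDir, seed = as.integer(seed),
    stages = c("simulate", "gate", "diversity", "screen", "dynamics"),
    simulate = list(nWells = 15L, noiseCV = 0.1, missingFraction = 0.2,
                    cellTimepoints = c(0, 72)),
    gate = list(controlArm = "DMSO"),
    diversity = list(logBase = "ln"),
    screen = list(k = 6L, nRestarts = 10L, ciLevels = c(0.75, 0.90),
                  ciRatio = c(1, 1)),
    dynamics = list(lambda = 1e-3,
                    hypotheses = c("darwinian_k14hi", "transition_mediated"))),
    class = "RunConfig")
}

#' Validate a run configuration against the expected schema
#'
#' @param config A \code{RunConfig} list.
#' @return \code{config}, invisibly; errors describe the first violation.
#' @export
validateRunConfig <- function(config) {
  req <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  req(is.list(config), "must be a list")
  req(is.character(config$outDir) && length(config$outDir) == 1L,
      "outDir must be a single path")
  req(is.numeric(config$seed) && length(config$seed) == 1L,
      "seed must be a single integer")
  known <- c("simulate", "gate", "diversity", "screen", "dynamics")
  req(all(config$stages %in% known),
      paste("stages must be among", paste(known, collapse = ", ")))
  s <- config$simulate
  req(is.numeric(s$nWells) && s$nWells >= 1, "simulate$nWells must be >= 1")
  req(is.numeric(s$noiseCV) && s$noiseCV >= 0, "simulate$noiseCV must be >= 0")
  req(is.numeric(s$missingFraction) && s$missingFraction >= 0 &&
        s$missingFraction < 1, "simulate$missingFraction must be in [0, 1)")
  req(config$diversity$logBase %in% c("ln", "2"),
      "diversity$logBase must be 'ln' or '2'")
  req(is.numeric(config$screen$k) && config$screen$k >= 2,
      "screen$k must be >= 2")
  req(is.numeric(config$dynamics$lambda) && config$dynamics$lambda >= 0,
      "dynamics$lambda must be >= 0")
  req(all(config$dynamics$hypotheses %in%
            c("darwinian_k14hi", "transition_mediated", "control")),
      "unknown hypothesis name")
  invisible(config)
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return \code{readRunConfig}: the config; \code{writeRunConfig}:
#'   \code{path} invisibly. Configs round-trip losslessly.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "RunConfig")
}

#' @rdname readRunConfig
#' @param config A \code{RunConfig}.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.hypoByName <- function(nm) {
  switch(nm,
         darwinian_k14hi = darwinianHypothesis(),
         transition_mediated = transitionHypothesis(),
         control = controlHypothesis(),
         stop("unknown hypothesis: ", nm))
}

#' Run the analysis pipeline from one configuration
#'
#' Executes the requested stages in dependency order, writing every
#' intermediate to \code{config$outDir} (CSV for tables, JSON for fits and
#' reports) and a \code{manifest.json} recording the config snapshot,
#' package version, per-stage seeds, output checksums, warnings and status.
#' Later stages read the files written by earlier ones, so partial runs are
#' supported; a stage failure is recorded and downstream stages are skipped.
#'
#' @param config A \code{RunConfig} (see \code{\link{defaultRunConfig}}).
#' @return The manifest, invisibly (list; also written to
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  validateRunConfig(config)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outDir, f)
  manifest <- list(config = unclass(config),
                   version = as.character(packageVersion("statefate")),
                   stages = list(), warnings = character(0))
  failed <- FALSE

  runStage <- function(name, files, fun) {
    if (failed || !(name %in% config$stages)) {
      if (name %in% config$stages)
        manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) e),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                sprintf("%s: %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      failed <<- TRUE
    } else {
      sums <- md5sum(vapply(files, out, character(1)))
      manifest$stages[[name]] <<- list(
        status = "ok", seed = childSeed(config$seed, match(name, config$stages)),
        outputs = as.list(setNames(unname(sums), files)))
    }
    invisible(NULL)
  }

  runStage("simulate", c("timecourse.csv", "cells.csv", "ground_truth.json",
                         "expression.csv", "genesets.gmt",
                         "dose_response.csv"), function() {
    seedS <- childSeed(config$seed, 1L)
    gtc <- groundTruthConfig(nWells = config$simulate$nWells,
                             noiseCV = config$simulate$noiseCV,
                             missingFraction = config$simulate$missingFraction,
                             seed = seedS)
    gen <- generateTimecourse(gtc)
    write.csv(gen$timecourse@data, out("timecourse.csv"), row.names = FALSE)

    tr <- gen$truth$trajectories
    tr <- tr[tr$timepoint_h %in% config$simulate$cellTimepoints, , drop = FALSE]
    sc <- rbind(
      data.frame(well_id = tr$well_id, arm = tr$arm,
                 timepoint_h = tr$timepoint_h, state = "K14hi",
                 count = tr$liveHi),
      data.frame(well_id = tr$well_id, arm = tr$arm,
                 timepoint_h = tr$timepoint_h, state = "K14lo",
                 count = tr$liveLo))
    cells <- generateCellTable(sc, gtc$intensityModel,
                               eduProb = c(K14hi = 0.3, K14lo = 0.3),
                               seed = childSeed(seedS, 2L))
    write.csv(cells, out("cells.csv"), row.names = FALSE)

    fx <- generateExpressionFixture(seed = childSeed(seedS, 3L))
    write.csv(data.frame(gene = rownames(fx$expr), fx$expr,
                         check.names = FALSE),
              out("expression.csv"), row.names = FALSE)
    writeGMT(fx$genesets, out("genesets.gmt"))

    dr <- rbind(
      cbind(agent = "A", generateMedianEffectData(1.2, 0.5,
            0.05 * 2^(0:6), cv = 0, seed = childSeed(seedS, 4L))),
      cbind(agent = "B", generateMedianEffectData(1.5, 1.0,
            0.05 * 2^(0:6), cv = 0, seed = childSeed(seedS, 5L))),
      cbind(agent = "combo", generateMedianEffectData(1.4, 0.3,
            0.05 * 2^(0:6), cv = 0, seed = childSeed(seedS, 6L))))
    write.csv(dr, out("dose_response.csv"), row.names = FALSE)

    truth <- list(
      params = lapply(gen$truth$params, function(p) as.list(p@rates)),
      initCounts = as.list(gtc$initCounts), timepoints = gtc$timepoints,
      nWells = gtc$nWells, seed = seedS)
    jsonlite::write_json(truth, out("ground_truth.json"), auto_unbox = TRUE,
                         digits = NA)
  })

  runStage("gate", c("thresholds.json", "state_frequencies.csv"), function() {
    cells <- read.csv(out("cells.csv"))
    gate <- computeGateThresholds(cells, config$gate$controlArm)
    lab <- assignProminentStates(cells, gate)
    fr <- stateFrequencies(cells, lab, groupKeys = c("arm", "timepoint_h"),
                           states = c("K14hi", "VIMhi", "K19hi", "TripleLow"))
    jsonlite::write_json(list(controlArm = gate@controlArm,
                              nCells = gate@nCells,
                              thresholds = as.list(gate@thresholds)),
                         out("thresholds.json"), auto_unbox = TRUE, digits = NA)
    write.csv(fr, out("state_frequencies.csv"), row.names = FALSE)
  })

  runStage("diversity", c("diversity.csv", "geneset_scores.csv"), function() {
    fr <- read.csv(out("state_frequencies.csv"))
    base <- if (config$diversity$logBase == "2") 2 else exp(1)
    dv <- diversityTable(fr, groupKeys = c("arm", "timepoint_h"), base = base)
    dv$logBase <- config$diversity$logBase
    write.csv(dv, out("diversity.csv"), row.names = FALSE)

    ex <- read.csv(out("expression.csv"), check.names = FALSE)
    expr <- as.matrix(ex[, -1, drop = FALSE])
    rownames(expr) <- ex$gene
    gs <- readGMT(out("genesets.gmt"))
    scores <- data.frame(sample = colnames(expr),
                         cumulativeZ = cumulativeGenesetZscore(expr, gs),
                         betweenGenesetVariance = betweenGenesetVariance(expr, gs))
    write.csv(scores, out("geneset_scores.csv"), row.names = FALSE)
  })

  runStage("screen", c("response_profiles.csv", "clusters.csv",
                       "combination_index.json"), function() {
    seedK <- childSeed(config$seed, 4L)
    rp <- generateResponseProfiles(seed = seedK)
    cl <- clusterResponseProfiles(rp$profiles, k = config$screen$k,
                                  seed = childSeed(seedK, 1L),
                                  nRestarts = config$screen$nRestarts)
    write.csv(data.frame(drug = rownames(rp$profiles), rp$profiles,
                         check.names = FALSE),
              out("response_profiles.csv"), row.names = FALSE)
    write.csv(data.frame(drug = names(cl$cluster), cluster = cl$cluster,
                         generatingGroup = rp$groups),
              out("clusters.csv"), row.names = FALSE)

    dr <- read.csv(out("dose_response.csv"))
    fits <- lapply(split(dr, dr$agent), function(x)
      fitMedianEffect(x$dose, x$fa))
    ci <- combinationIndex(fits$A, fits$B, fits$combo,
                           ratio = config$screen$ciRatio,
                           effectLevels = config$screen$ciLevels)
    jsonlite::write_json(
      list(fits = lapply(fits, function(f) f[c("m", "Dm", "r2", "n")]),
           ci = as.data.frame(unclass(ci))),
      out("combination_index.json"), auto_unbox = TRUE, digits = NA)
  })

  runStage("dynamics", c("fitted_rates.json", "hypothesis_comparison.json",
                         "fold_changes.csv"), function() {
    tcd <- read.csv(out("timecourse.csv"))
    tc <- TimeCourse(tcd, controlArm = config$gate$controlArm)
    hyps <- lapply(setNames(config$dynamics$hypotheses,
                            config$dynamics$hypotheses), .hypoByName)
    cmp <- compareHypotheses(tc, hyps, lambda = config$dynamics$lambda)
    jsonlite::write_json(
      lapply(cmp$fits, function(f) list(
        hypothesis = f@hypothesis@name, rates = as.list(f@params@rates),
        lambda = f@diagnostics$lambda, iterations = f@diagnostics$iterations,
        converged = f@diagnostics$converged)),
      out("fitted_rates.json"), auto_unbox = TRUE, digits = NA)
    fc <- do.call(rbind, lapply(names(cmp$fcSim), function(nm)
      cbind(hypothesis = nm, cmp$fcSim[[nm]])))
    fc <- rbind(fc, cbind(hypothesis = "observed", cmp$fcObs))
    write.csv(fc, out("fold_changes.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(table = cmp$table, best = cmp$best, arm = cmp$arm,
           logBase = config$diversity$logBase,
           allocationRules = vapply(hyps, function(h) h@allocation,
                                    character(1)),
           lambda = config$dynamics$lambda),
      out("hypothesis_comparison.json"), auto_unbox = TRUE, digits = NA)
  })

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
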