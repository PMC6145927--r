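test_that("system matrix structure and mass bookkeeping", {
  expect_equal(unname(systemMatrix(rateParameters())), diag(3))
  A <- systemMatrix(rateParameters(kHL = 0.2))
  expect_equal(unname(A[, 1]), c(0.8, 0.2, 0))
  expect_equal(unname(A[, 2]), c(0, 1, 0))
  expect_equal(unname(A[, 3]), c(0, 0, 1))
  # live column sums are 1 + a: division is the only mass creation
  for (s in 1:10) {
    r <- withr::with_seed(s, runif(6, 0, 0.3))
    p <- rateParameters(r[1], r[2], r[3], r[4], r[5], r[6])
    A <- systemMatrix(p)
    expect_equal(unname(colSums(A)[1:2]), unname(c(1 + r[1], 1 + r[2])),
                 tolerance = 1e-12)
    expect_equal(unname(A[, 3]), c(0, 0, 1))
  }
  expect_error(rateParameters(dHi = 0.9, kHL = 0.9), "budget")
  expect_error(rateParameters(aHi = 1.2), "\\[0, 1\\]")
})

test_that("deterministic simulation: decay, linearity, dead monotone", {
  cons <- simulateDeterministic(rateParameters(), c(10, 20, 5), 4)
  expect_true(all(cons[, "nHi"] == 10 & cons[, "nLo"] == 20 &
                    cons[, "nDead"] == 5))
  s <- simulateDeterministic(rateParameters(dLo = 0.1), c(0, 1000, 0), 6)
  expect_equal(unname(s[7, "nLo"]), 1000 * 0.9^6, tolerance = 1e-12)
  expect_equal(unname(s[7, "nDead"]), 1000 - 1000 * 0.9^6, tolerance = 1e-12)
  p <- rateParameters(0.1, 0.05, 0.02, 0.08, 0.1, 0.05)
  s1 <- simulateDeterministic(p, c(100, 200, 10), 5)
  s2 <- simulateDeterministic(p, 2 * c(100, 200, 10), 5)
  expect_equal(2 * s1, s2, tolerance = 1e-12)
  expect_true(all(diff(s1[, "nDead"]) >= 0))
  # total growth each step is exactly a_hi n_hi + a_lo n_lo
  growth <- diff(rowSums(s1))
  expect_equal(growth, 0.1 * s1[1:5, "nHi"] + 0.05 * s1[1:5, "nLo"],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(simulateDeterministic(p, c(-1, 0, 0), 2), "nonnegative")
})

test_that("compartment estimation implements the allocation rules", {
  mk <- function(df) TimeCourse(data.frame(
    well_id = "w1", arm = "drug", timepoint_h = c(0, 12),
    count_k14hi = c(400, 400), count_k14lo = c(600, 600),
    death_fraction = c(0, df), observed = TRUE), controlArm = "DMSO")
  darw <- measurements(estimateCompartments(mk(0.2), darwinianHypothesis()))
  expect_equal(darw[2, c("nHi", "nLo", "nDead")],
               data.frame(nHi = 400, nLo = 400, nDead = 200),
               ignore_attr = TRUE)
  trans <- measurements(estimateCompartments(mk(0.2), transitionHypothesis()))
  expect_equal(trans[2, c("nHi", "nLo", "nDead")],
               data.frame(nHi = 320, nLo = 480, nDead = 200),
               ignore_attr = TRUE)
  # zero death: live equals measured, dead identically zero
  none <- measurements(estimateCompartments(mk(0), darwinianHypothesis()))
  expect_equal(none$nHi, c(400, 400))
  expect_equal(none$nLo, c(600, 600))
  expect_true(all(none$nDead == 0))
  expect_error(estimateCompartments(mk(1.2), darwinianHypothesis()),
               "death fraction")

  # control arm uses the 50/50 split under any hypothesis
  tcc <- TimeCourse(data.frame(
    well_id = "c1", arm = "DMSO", timepoint_h = c(0, 12),
    count_k14hi = c(400, 400), count_k14lo = c(600, 600),
    death_fraction = c(0, 0.2), observed = TRUE))
  ctrl <- measurements(estimateCompartments(tcc, darwinianHypothesis()))
  expect_equal(ctrl[2, c("nHi", "nLo", "nDead")],
               data.frame(nHi = 300, nLo = 500, nDead = 200),
               ignore_attr = TRUE)

  # negative estimates are floored at zero with a warning
  tcn <- TimeCourse(data.frame(
    well_id = "w1", arm = "drug", timepoint_h = c(0, 12),
    count_k14hi = c(400, 100), count_k14lo = c(600, 100),
    death_fraction = c(0, 0.9), observed = TRUE), controlArm = "DMSO")
  expect_warning(est <- estimateCompartments(tcn, darwinianHypothesis()),
                 "floored")
  expect_equal(measurements(est)$nLo[2], 0)

  # dead compartment accumulates and is nondecreasing within a well
  tc3 <- TimeCourse(data.frame(
    well_id = "w1", arm = "drug", timepoint_h = c(0, 12, 24),
    count_k14hi = c(400, 400, 400), count_k14lo = c(600, 600, 600),
    death_fraction = c(0, 0.2, 0.1), observed = TRUE), controlArm = "DMSO")
  est3 <- measurements(estimateCompartments(tc3, transitionHypothesis()))
  expect_equal(est3$nDead, c(0, 200, 300))
})

test_that("noiseless complete-data fit recovers the generating rates", {
  truth <- rateParameters(aHi = 0.02, aLo = 0.02, dHi = 0.03, dLo = 0.03,
                          kHL = 0.01, kLH = 0.2)
  traj <- deterministicTraj(truth, list(c(540, 1460, 0), c(800, 1200, 0),
                                        c(300, 1700, 0)))
  fit <- fitDynamics(traj, transitionHypothesis(), lambda = 1e-3)
  expect_lt(max(abs(rates(fit) - rates(truth))), 1e-6)
  expect_equal(diagnostics(fit)$iterations, 1)
})

test_that("alternating fit equals the direct constrained solve on complete data", {
  truth <- rateParameters(aHi = 0.05, aLo = 0.05, dHi = 0.02, dLo = 0.08,
                          kHL = 0.04, kLH = 0.12)
  hyp <- hypothesisSpec("free", allocation = "proportional")
  traj <- deterministicTraj(truth, list(c(540, 1460, 0), c(900, 1100, 0),
                                        c(200, 1800, 0)))
  fit <- fitDynamics(traj, hyp, lambda = 1e-3)
  oracle <- directFitOracle(traj, hyp, arm = "treated", lambda = 1e-3)
  expect_lt(max(abs(rates(fit) - oracle)), 1e-9)
})

test_that("constrained quadratic solver agrees with an independent solver", {
  # Darwinian-truth data fitted under the transition spec push kHL against
  # its lower bound; on complete data the two objectives coincide, so the
  # active-set solution can be compared against L-BFGS-B directly
  cfg <- converseConfig(3)
  cfg$missingFraction <- 0
  gen <- generateTimecourse(cfg)
  est <- suppressWarnings(estimateCompartments(gen$timecourse,
                                               transitionHypothesis()))
  fit <- fitDynamics(est, transitionHypothesis(), arm = "treated")
  expect_equal(unname(rates(fit)["kHL"]), 0)  # bound active in this instance

  d <- measurements(est)
  d <- d[d$arm == "treated", ]
  obj <- function(th) {
    # th = (a, d, kHL, kLH) under the transition ties; the system matrix is
    # assembled inline so the optimizer may roam the whole unit box
    a <- th[1]; dd <- th[2]; kHL <- th[3]; kLH <- th[4]
    A <- rbind(c(1 + a - dd - kHL, kLH, 0),
               c(kHL, 1 + a - dd - kLH, 0),
               c(dd, dd, 1))
    J <- 1e-3 * sum(c(a, a, dd, dd, kHL, kLH)^2)
    for (w in unique(d$well_id)) {
      Y <- as.matrix(d[d$well_id == w, c("nHi", "nLo", "nDead")])
      for (t in seq_len(nrow(Y) - 1))
        J <- J + sum((Y[t + 1, ] - drop(A %*% Y[t, ]))^2)
    }
    J
  }
  ref <- optim(c(0.05, 0.05, 0.05, 0.05), obj, method = "L-BFGS-B",
               lower = 0, upper = 1, control = list(factr = 10))
  r <- rates(fit)
  expect_equal(unname(r[c("aHi", "dHi", "kHL", "kLH")]), unname(ref$par),
               tolerance = 1e-5)
  expect_lte(obj(c(r["aHi"], r["dHi"], r["kHL"], r["kLH"])),
             ref$value * (1 + 1e-9))
})

test_that("masked noiseless data: recovery, monotone objective, convergence", {
  truth <- rateParameters(aHi = 0.02, aLo = 0.02, dHi = 0.03, dLo = 0.03,
                          kHL = 0.01, kLH = 0.2)
  traj <- deterministicTraj(truth, list(c(540, 1460, 0), c(800, 1200, 0),
                                        c(300, 1700, 0)))
  idx <- withr::with_seed(1, sample(which(traj@data$timepoint_h > 0), 4))
  masked <- maskTraj(traj, idx)
  fit <- fitDynamics(masked, transitionHypothesis(), lambda = 1e-3)
  expect_lt(max(abs(rates(fit) - rates(truth))), 1e-3)
  obj <- diagnostics(fit)$objective
  expect_true(all(diff(obj) <= 1e-8 * (1 + head(obj, -1))))
  expect_true(diagnostics(fit)$converged)
})

test_that("heavy regularization shrinks all free rates to zero", {
  cfg <- groundTruthConfig(seed = 2)
  gen <- generateTimecourse(cfg)
  est <- suppressWarnings(estimateCompartments(gen$timecourse,
                                               transitionHypothesis()))
  fit <- fitDynamics(est, transitionHypothesis(), arm = "treated",
                     lambda = 1e12)
  expect_true(all(rates(fit) < 1e-3))
})

test_that("fitted parameters satisfy the hypothesis constraints exactly", {
  cfg <- groundTruthConfig(seed = 8)
  gen <- generateTimecourse(cfg)
  for (hyp in list(darwinianHypothesis(), transitionHypothesis())) {
    est <- suppressWarnings(estimateCompartments(gen$timecourse, hyp))
    fit <- fitDynamics(est, hyp, arm = "treated")
    r <- rates(fit)
    expect_equal(unname(r["aHi"]), unname(r["aLo"]), tolerance = 1e-12)
    for (nm in names(hyp@fixes))
      expect_equal(unname(r[nm]), unname(hyp@fixes[[nm]]), tolerance = 1e-12)
    if (hyp@name == "transition_mediated")
      expect_equal(unname(r["dHi"]), unname(r["dLo"]), tolerance = 1e-12)
  }
  expect_error(fitDynamics(estimateCompartments(gen$timecourse,
                                                transitionHypothesis()),
                           transitionHypothesis()),
               "specify")
})

test_that("proportion fold change: identity, ratios, transition monotonicity", {
  p <- rateParameters(0.1, 0.1, 0.02, 0.02, 0.03, 0.03)
  s <- simulateDeterministic(p, c(500, 500, 0), 5)
  fc <- proportionFoldChange(s, s)
  expect_true(all(abs(fc$fcHi - 1) < 1e-12 & abs(fc$fcLo - 1) < 1e-12))

  sT <- matrix(c(800, 200, 0), 1, 3,
               dimnames = list(NULL, c("nHi", "nLo", "nDead")))
  sC <- matrix(c(200, 800, 0), 1, 3,
               dimnames = list(NULL, c("nHi", "nLo", "nDead")))
  expect_equal(proportionFoldChange(sT, sC)$fcHi, 4)

  # pure transitions, no death/division: fcHi increases monotonically toward
  # the net flux direction
  trans <- rateParameters(kLH = 0.2, kHL = 0.01)
  none <- rateParameters()
  sTr <- simulateDeterministic(trans, c(270, 730, 0), 6)
  sCt <- simulateDeterministic(none, c(270, 730, 0), 6)
  fc2 <- proportionFoldChange(sTr, sCt)
  expect_true(all(diff(fc2$fcHi) > 0))
  expect_error(proportionFoldChange(sTr[1:3, ], sCt), "time grid")
})

test_that("hypothesis comparison identifies the generating mechanism", {
  gen <- generateTimecourse(groundTruthConfig(seed = 101))
  cmp <- suppressWarnings(compareHypotheses(gen$timecourse))
  expect_equal(cmp$best, "transition_mediated")
  expect_true(all(cmp$table$endpointErr >= 0))
  expect_equal(nrow(cmp$fcObs), 7)

  genC <- generateTimecourse(converseConfig(102))
  cmpC <- suppressWarnings(compareHypotheses(genC$timecourse))
  expect_equal(cmpC$best, "darwinian_k14hi")

  expect_error(compareHypotheses(gen$timecourse,
                                 list(a = darwinianHypothesis())),
               ">= 2")
})
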