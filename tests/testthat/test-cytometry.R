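mkCells <- function(k19, k14, vim, arm = "DMSO", well = "w1") {
  n <- length(k19)
  data.frame(cell_id = seq_len(n), well_id = well, arm = arm, timepoint_h = 0,
             k19_mfi = k19, k14_mfi = k14, vim_mfi = vim,
             edu_pos = 0L, dying = 0L, true_state = NA_character_)
}

test_that("gate thresholds are pooled control-arm means", {
  cells <- mkCells(k19 = c(5, 5, 5), k14 = c(1, 2, 3), vim = c(2, 4, 6))
  g <- computeGateThresholds(cells, "DMSO")
  expect_equal(unname(thresholds(g)["K14"]), 2)
  expect_equal(unname(thresholds(g)["VIM"]), 4)

  one <- computeGateThresholds(cells[2, ], "DMSO")
  expect_equal(unname(thresholds(one)), c(5, 2, 4))

  expect_error(computeGateThresholds(cells, "nope"), "no")

  # dying cells are excluded from threshold computation
  cells$dying[3] <- 1L
  g2 <- computeGateThresholds(cells, "DMSO")
  expect_equal(unname(thresholds(g2)["K14"]), 1.5)
})

test_that("thresholds on the synthetic fixture match the generator means", {
  sc <- data.frame(well_id = "c", arm = "DMSO", timepoint_h = 0,
                   state = c("K14hi", "K14lo"), count = c(2700, 7300))
  cells <- generateCellTable(sc, seed = 21)
  g <- computeGateThresholds(cells, "DMSO")
  # lognormal mean = location * exp(spread^2 / 2), mixed over states
  im <- defaultIntensityModel()
  mixMean <- function(mk) {
    m <- vapply(c("K14hi", "K14lo"), function(st) {
      p <- im[[st]][[mk]]; p[1] * exp(p[2]^2 / 2)
    }, numeric(1))
    0.27 * m[1] + 0.73 * m[2]
  }
  for (mk in c("K19", "K14", "VIM")) {
    col <- c(K19 = "k19_mfi", K14 = "k14_mfi", VIM = "vim_mfi")[[mk]]
    se <- sd(cells[[col]]) / sqrt(nrow(cells))
    expect_lt(abs(thresholds(g)[[mk]] - mixMean(mk)), 3 * se)
  }
})

test_that("combinatorial gating enumerates all patterns with strict thresholds", {
  g <- new("GateThresholds", thresholds = c(K19 = 10, K14 = 10, VIM = 10),
           controlArm = "DMSO", nCells = 1L)
  below <- mkCells(1, 1, 1)
  expect_equal(stateLabels(assignCombinatorialStates(below, g)),
               "K19-/K14-/VIM-")
  # MFI exactly at the threshold is negative ("exceeding" is strict)
  tie <- mkCells(10, 10, 10)
  expect_equal(stateLabels(assignCombinatorialStates(tie, g)),
               "K19-/K14-/VIM-")
  # one cell per +/- pattern -> 8 distinct labels
  pats <- expand.grid(k19 = c(5, 15), k14 = c(5, 15), vim = c(5, 15))
  cells <- mkCells(pats$k19, pats$k14, pats$vim)
  labs <- stateLabels(assignCombinatorialStates(cells, g))
  expect_equal(length(unique(labs)), 8)
  expect_error(assignCombinatorialStates(cells[, -5], g), "missing")
})

test_that("prominent-state priority rule matches its definition", {
  g <- new("GateThresholds", thresholds = c(K19 = 10, K14 = 10, VIM = 10),
           controlArm = "DMSO", nCells = 1L)
  # K14-high and K19-high -> K14hi (K19hi/K14hi cells are K14hi)
  expect_equal(stateLabels(assignProminentStates(mkCells(20, 20, 1), g)),
               "K14hi")
  expect_equal(stateLabels(assignProminentStates(mkCells(1, 1, 1), g)),
               "TripleLow")
  # VIM-high, K14-low, K19-high -> VIMhi
  expect_equal(stateLabels(assignProminentStates(mkCells(20, 1, 20), g)),
               "VIMhi")
  expect_equal(stateLabels(assignProminentStates(mkCells(20, 1, 1), g)),
               "K19hi")
})

test_that("prominent partition and combinatorial collapse agree on random cells", {
  cells <- randomCellTable(10000, seed = 31)
  g <- computeGateThresholds(cells, "DMSO")
  prom <- stateLabels(assignProminentStates(cells, g))
  comb <- stateLabels(assignCombinatorialStates(cells, g))
  # exhaustive and exclusive partition
  counts <- table(factor(prom, levels = c("K14hi", "VIMhi", "K19hi",
                                          "TripleLow")))
  expect_equal(sum(counts), nrow(cells))
  expect_identical(collapseToProminent(comb), prom)
})

test_that("gating is invariant to row order", {
  cells <- randomCellTable(500, seed = 7)
  perm <- withr::with_seed(8, sample(nrow(cells)))
  g1 <- thresholds(computeGateThresholds(cells, "DMSO"))
  g2 <- thresholds(computeGateThresholds(cells[perm, ], "DMSO"))
  expect_equal(g1, g2)
  fr1 <- stateFrequencies(cells,
                          assignProminentStates(cells,
                                                computeGateThresholds(cells, "DMSO")))
  fr2 <- stateFrequencies(cells[perm, ],
                          assignProminentStates(cells[perm, ],
                                                computeGateThresholds(cells[perm, ], "DMSO")))
  expect_equal(fr1[order(fr1$state), ], fr2[order(fr2$state), ],
               ignore_attr = TRUE)
})

test_that("state frequencies sum to one and report absent states as zero", {
  cells <- mkCells(c(20, 1, 20, 1), c(20, 1, 1, 1), c(1, 20, 1, 1))
  g <- new("GateThresholds", thresholds = c(K19 = 10, K14 = 10, VIM = 10),
           controlArm = "DMSO", nCells = 1L)
  lab <- assignProminentStates(cells, g)
  fr <- stateFrequencies(cells, lab)
  expect_equal(sort(fr$Pi), rep(0.25, 4))

  allOne <- stateFrequencies(cells, rep("K14hi", 4),
                             states = c("K14hi", "VIMhi"))
  expect_equal(allOne$Pi, c(1, 0))
  expect_equal(sum(allOne$Pi), 1)
})

test_that("frequencies on a noiseless synthetic well equal generator proportions", {
  sc <- data.frame(well_id = "w1", arm = "t", timepoint_h = 0,
                   state = c("K14hi", "K14lo"), count = c(300, 700))
  cells <- generateCellTable(sc, seed = 2)
  fr <- stateFrequencies(cells, cells$true_state, groupKeys = "well_id")
  expect_equal(fr$Pi[fr$state == "K14hi"], 0.3)
  expect_equal(fr$Pi[fr$state == "K14lo"], 0.7)
})

test_that("marker Z-score change against control wells", {
  ctrl <- rbind(mkCells(10, 10, 10, well = "c1"),
                mkCells(12, 12, 12, well = "c2"),
                mkCells(14, 14, 14, well = "c3"))
  trt <- mkCells(16, 16, 16, arm = "drug", well = "t1")
  cells <- rbind(ctrl, trt)
  expect_equal(markerZscoreChange(cells, "t1", c("c1", "c2", "c3"), "K14"), 2)
  trt0 <- mkCells(12, 12, 12, arm = "drug", well = "t0")
  expect_equal(markerZscoreChange(rbind(ctrl, trt0), "t0",
                                  c("c1", "c2", "c3"), "K14"), 0)
  # one control SD above -> Z = 1
  trt1 <- mkCells(14, 14, 14, arm = "drug", well = "t2")
  expect_equal(markerZscoreChange(rbind(ctrl, trt1), "t2",
                                  c("c1", "c2", "c3"), "K19"), 1)
  expect_error(markerZscoreChange(cells, "t1", "c1", "K14"), ">= 2")
  same <- rbind(mkCells(10, 10, 10, well = "c1"),
                mkCells(10, 10, 10, well = "c2"), trt)
  expect_error(markerZscoreChange(same, "t1", c("c1", "c2"), "K14"),
               "spread")
})

test_that("flagged-cell fractions per state", {
  labels <- c("K14hi", "K14hi", "K14hi", "K14hi", "VIMhi")
  fr <- flagFractionByState(labels, c(1, 0, 0, 0, 1))
  expect_equal(fr$fraction[fr$state == "K14hi"], 0.25)
  expect_equal(fr$fraction[fr$state == "overall"], 0.4)
  allF <- flagFractionByState(labels, rep(1, 5))
  expect_true(all(allF$fraction == 1))
  withEmpty <- flagFractionByState(labels, c(1, 0, 0, 0, 1),
                                   states = c("K14hi", "VIMhi", "K19hi"))
  expect_true(is.na(withEmpty$fraction[withEmpty$state == "K19hi"]))
  expect_error(flagFractionByState(labels, c(2, 0, 0, 0, 1)), "binary")
})

test_that("per-state flag fractions recover a shared event probability", {
  n <- 4000
  cells <- randomCellTable(n, seed = 12)
  flag <- withr::with_seed(13, rbinom(n, 1, 0.3))
  g <- computeGateThresholds(cells, "DMSO")
  lab <- assignProminentStates(cells, g)
  fr <- flagFractionByState(lab, flag)
  fr <- fr[fr$state != "overall" & fr$n > 0, ]
  ciHalf <- 1.96 * sqrt(0.3 * 0.7 / fr$n)
  expect_true(all(abs(fr$fraction - 0.3) <= ciHalf + 0.02))
})
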