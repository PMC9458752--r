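# helper: build a trial table by hand from a per-eye x orientation count
# matrix (constant across repeats) and a blank count
handTrials <- function(counts, blankCount, protocol = stimProtocol(),
                       unit = "u1", mouse = "m1") {
  orients <- protocolOrientations(protocol)
  reps <- protocol@repeatsPerCondition
  rows <- expand.grid(rep = seq_len(reps), orientation_deg = orients,
                      eye = protocol@eyes, stringsAsFactors = FALSE)
  rows$spike_count <- mapply(function(e, o) counts[e, as.character(o)],
                             rows$eye, rows$orientation_deg)
  blank <- data.frame(rep = seq_len(nrow(rows)), orientation_deg = NA,
                      eye = "blank", spike_count = blankCount)
  tt <- rbind(rows, blank)
  data.frame(mouse_id = mouse, unit_id = unit, eye = tt$eye,
             orientation_deg = tt$orientation_deg, "repeat" = tt$rep,
             spike_count = tt$spike_count,
             stim_s = protocol@stimDurationS,
             trial_s = protocol@trialDurationS, check.names = FALSE)
}

test_that("tuning computes baseline-subtracted rates and preferred orientation", {
  p <- stimProtocol()
  orients <- protocolOrientations(p)
  cmat <- matrix(4, 2, 12, dimnames = list(p@eyes, orients))

  # all counts equal across orientations and blank -> all evoked rates 0
  tun <- tuningFromTrials(handTrials(cmat, 4), p)
  expect_true(all(abs(tun@evokedRateHz) < 1e-12))
  expect_equal(tun@blankRateHz, 2)  # 4 spikes / 2 s

  # counts double at 90 deg for the contra eye -> contra preferred 90
  cmat2 <- cmat; cmat2["contra", "90"] <- 8
  tun2 <- tuningFromTrials(handTrials(cmat2, 4), p)
  expect_equal(unname(tun2@preferredDeg["contra"]), 90)
  expect_equal(unname(tun2@preferredEvokedHz["contra"]), 2)  # (8-4)/2 s

  # ties break toward the lowest orientation value
  expect_equal(unname(tun@preferredDeg["contra"]), 0)

  noBlank <- handTrials(cmat, 4)
  noBlank <- noBlank[noBlank$eye != "blank", ]
  expect_error(tuningFromTrials(noBlank, p), "blank")
})

test_that("planted preferred orientation is recovered at SNR 3", {
  # drive/baseline = 3, preferred 150 deg, no across-unit spread
  p <- stimProtocol()
  nSim <- 500
  tr <- odGroundTruth(contraDriveHz = 6, ipsiDriveHz = 6, baselineRateHz = 2,
                      driveSdLog = 0)
  sim <- genODDataset(p, tr, nSim, 1, seed = 42)
  units <- sim$truth@units
  ut <- mouseODSummary(sim$trials, p)$units
  # recompute each unit's global preferred orientation via tuningFromTrials
  # on the subset of simulated units planted at 150 deg
  planted <- units$unit_id[units$preferred_deg == 150]
  hits <- vapply(planted, function(u) {
    tun <- tuningFromTrials(sim$trials[sim$trials$unit_id == u, ], p)
    # the tuning is shared across eyes here, so the unit's preferred
    # orientation is estimated from the eye-pooled evoked tuning curve
    glob <- tun@orientationsDeg[which.max(colMeans(tun@evokedRateHz))]
    glob == 150
  }, logical(1))
  expect_gte(length(planted), 20)
  expect_gte(mean(hits), 0.95)
})

test_that("the 50% inclusion rule uses raw rates against blank", {
  p <- stimProtocol()
  orients <- protocolOrientations(p)
  base <- matrix(4, 2, 12, dimnames = list(p@eyes, orients))

  mk <- function(prefHz, blankHz) {
    m <- base
    m[] <- blankHz * p@stimDurationS
    m["contra", "0"] <- prefHz * p@stimDurationS
    tuningFromTrials(handTrials(m, blankHz * p@stimDurationS), p)
  }
  expect_true(passesInclusion(mk(3.1, 2)))    # 1.55x blank
  expect_false(passesInclusion(mk(2.9, 2)))   # 1.45x blank
  expect_false(passesInclusion(mk(0, 0)))     # no response at all
  expect_true(passesInclusion(mk(0.5, 0)))    # blank 0: any response passes
})

test_that("ODI arithmetic and domain errors", {
  expect_equal(computeODI(10, 0), -1)
  expect_equal(computeODI(5, 5), 0)
  expect_equal(computeODI(3, 7), 0.4)
  expect_equal(computeODI(c(10, 5, 3), c(0, 5, 7)), c(-1, 0, 0.4))
  expect_error(computeODI(0, 0), "undefined")
  expect_error(computeODI(-1, 2), ">= 0")
})

test_that("seven-category scheme partitions [-1, 1] monotonically", {
  expect_equal(odiToCategory(-1), 1L)
  expect_equal(odiToCategory(0.4), 5L)
  expect_equal(odiToCategory(-0.75), 2L)  # half-open [lower, upper)
  expect_equal(odiToCategory(1), 7L)      # last bin closed at 1
  expect_error(odiToCategory(1.2), "\\[-1, 1\\]")

  odis <- sort(c(seq(-1, 1, by = 0.001),
                 c(-0.75, -0.45, -0.15, 0.15, 0.45, 0.75)))
  cats <- odiToCategory(odis)
  expect_true(all(cats %in% 1:7))            # every value maps to one bin
  expect_true(all(diff(cats) >= 0))          # non-decreasing in ODI
  expect_setequal(unique(cats), 1:7)
})

test_that("CBI matches anchors, symmetry, monotonicity and the unit-sum oracle", {
  expect_equal(computeCBI(c(20, 0, 0, 0, 0, 0, 0)), 1)
  expect_equal(computeCBI(c(0, 0, 0, 20, 0, 0, 0)), 0.5)
  expect_equal(computeCBI(c(0, 0, 0, 0, 0, 0, 20)), 0)
  expect_error(computeCBI(rep(0, 7)), "N = 0")

  # independent oracle: CBI as a mean of per-unit weights
  # (category weights 1, 2/3, 1/3, 0, -1/3, -2/3, -1, then (w + 1)/2)
  cbiOracle <- function(counts) {
    w <- c(1, 2 / 3, 1 / 3, 0, -1 / 3, -2 / 3, -1)
    units <- rep(1:7, counts)
    mean((w[units] + 1) / 2)
  }
  set.seed(20)
  for (i in 1:200) {
    counts <- rpois(7, 5)
    if (sum(counts) == 0) counts[4] <- 1
    expect_equal(computeCBI(counts), cbiOracle(counts), tolerance = 1e-12)
    expect_equal(computeCBI(counts) + computeCBI(rev(counts)), 1,
                 tolerance = 1e-12)  # mirror symmetry
  }
  # moving one unit from category k to k+1 never increases CBI
  for (k in 1:6) {
    counts <- rep(3, 7)
    moved <- counts
    moved[k] <- moved[k] - 1
    moved[k + 1] <- moved[k + 1] + 1
    expect_lte(computeCBI(moved), computeCBI(counts) + 1e-12)
  }
})

test_that("the pipeline is equivariant under unit relabeling", {
  p <- stimProtocol()
  sim <- genODDataset(p, odGroundTruth(), 8, 2, seed = 9)
  base <- mouseODSummary(sim$trials, p)
  relab <- sim$trials
  map <- setNames(sprintf("zz_%s", unique(relab$unit_id)),
                  unique(relab$unit_id))
  relab$unit_id <- unname(map[relab$unit_id])
  new <- mouseODSummary(relab, p)
  ord1 <- order(map[base$units$unit_id])
  expect_equal(base$units$odi[ord1], new$units$odi)
  expect_equal(base$units$included[ord1], new$units$included)
  expect_equal(base$mice[c("N", "cbi")], new$mice[c("N", "cbi")])
})

test_that("identical ND and MD inputs give null group statistics", {
  p <- stimProtocol()
  sim <- genODDataset(p, odGroundTruth(), 10, 3, seed = 4)
  g <- odGroupAnalysis(sim$trials, sim$trials, p)
  expect_equal(g@ksTest@statistic, 0)
  expect_equal(g@cbiTest@statistic, 0)
  expect_equal(g@categoryHistogram["ND", ], g@categoryHistogram["MD", ])
})

test_that("a 50% deprived-eye reduction lowers MD CBI (power check)", {
  p <- stimProtocol()
  nRep <- 40
  lower <- vapply(seq_len(nRep), function(i) {
    nd <- genODDataset(p, odGroundTruth(), 30, 7, seed = 2 * i)
    md <- genODDataset(p, odGroundTruth(mdShift = 0.5), 30, 7,
                       seed = 2 * i + 1)
    g <- odGroupAnalysis(nd$trials, md$trials, p)
    ms <- g@mouseSummaries
    mean(ms$cbi[ms$condition == "MD"]) < mean(ms$cbi[ms$condition == "ND"])
  }, logical(1))
  expect_gte(mean(lower), 0.95)
})

test_that("mice without included units are dropped with a warning", {
  p <- stimProtocol()
  good <- genODDataset(p, odGroundTruth(), 10, 2, seed = 4)$trials
  dead <- genODDataset(p, odGroundTruth(contraDriveHz = 0, ipsiDriveHz = 0,
                                        baselineRateHz = 0),
                       5, 1, seed = 5, mouseIds = "dead")$trials
  expect_warning(g <- odGroupAnalysis(rbind(good, dead), good, p), "dropped")
  expect_true("dead" %in% g@droppedMice)
  expect_false("dead" %in% g@mouseSummaries$mouse_id)
})
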