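test_that("generators are deterministic given a seed and restore RNG state", {
  p <- stimProtocol()
  a <- genODDataset(p, odGroundTruth(), 4, 2, seed = 7)
  b <- genODDataset(p, odGroundTruth(), 4, 2, seed = 7)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth@units, b$truth@units)
  set.seed(99)
  before <- .Random.seed
  invisible(genODDataset(p, odGroundTruth(), 2, 1, seed = 3))
  invisible(genMiniTruth(5, seed = 3))
  invisible(genLTPSession(-0.2, 1.5, seed = 3))
  expect_identical(.Random.seed, before)

  t1 <- genMiniTruth(10, seed = 5)
  t2 <- genMiniTruth(10, seed = 5)
  expect_identical(t1@eventTimesS, t2@eventTimesS)
  s1 <- genLSPSDataset(lspsGrid(), defaultLSPSProfile(), nCells = 1, seed = 4)
  s2 <- genLSPSDataset(lspsGrid(), defaultLSPSProfile(), nCells = 1, seed = 4)
  expect_identical(s1$recordings[[1]]@sweeps[[40]]@samples,
                   s2$recordings[[1]]@sweeps[[40]]@samples)
})

test_that("OD trial tables have the declared design and sign convention", {
  p <- stimProtocol()
  sim <- genODDataset(p, odGroundTruth(), 3, 2, seed = 1)
  tt <- sim$trials
  expect_setequal(names(tt), c("mouse_id", "unit_id", "eye",
                               "orientation_deg", "repeat", "spike_count",
                               "stim_s", "trial_s"))
  stim <- tt[tt$eye != "blank", ]
  # one row per unit x eye x orientation x repeat, plus one blank per trial
  expect_equal(nrow(stim), 6 * 2 * 12 * 3)
  expect_equal(sum(tt$eye == "blank"), 6 * 2 * 12 * 3)
  expect_setequal(unique(stim$eye), c("contra", "ipsi"))

  # contra-dominated truth without MD must yield negative mean ODI
  # (ODI = (IE - CE)/(IE + CE): contra dominance is negative)
  strong <- odGroundTruth(contraDriveHz = 20, ipsiDriveHz = 2, mdShift = 0)
  sim2 <- genODDataset(p, strong, 20, 2, seed = 2)
  ut <- mouseODSummary(sim2$trials, p)$units
  expect_lt(mean(ut$odi[ut$included]), 0)
})

test_that("zero drive leaves inclusion at the chance level of Poisson noise", {
  p <- stimProtocol()
  flat <- odGroundTruth(contraDriveHz = 0, ipsiDriveHz = 0,
                        baselineRateHz = 2, mdShift = 0)
  sim <- genODDataset(p, flat, 250, 4, seed = 11)
  ut <- mouseODSummary(sim$trials, p)$units
  # preferred-orientation rate is the max of 24 Poisson means (3 trials of
  # baseline 2 Hz x 2 s); the 1.5x-blank rule is rarely met by chance:
  # Monte-Carlo of the chance level under the same design
  set.seed(1)
  chance <- mean(replicate(4000, {
    m <- matrix(rpois(24 * 3, 4), 3) / 2
    b <- mean(rpois(72, 4)) / 2
    if (b > 0) max(colMeans(m)) >= 1.5 * b else max(colMeans(m)) > 0
  }))
  expect_lt(mean(ut$included), chance + 3 *
              sqrt(chance * (1 - chance) / nrow(ut)) + 0.03)
  expect_gt(chance, mean(ut$included) - 3 *
              sqrt(chance * (1 - chance) / 4000) - 0.03)
})

test_that("doubling an eye's drive moves expected ODI monotonically", {
  p <- stimProtocol()
  odis <- sapply(c(2, 4, 8, 16), function(d) {
    tr <- odGroundTruth(contraDriveHz = 5, ipsiDriveHz = d, driveSdLog = 0)
    ut <- mouseODSummary(genODDataset(p, tr, 60, 1, seed = 5)$trials, p)$units
    mean(ut$odi[ut$included])
  })
  expect_true(all(diff(odis) > 0))
})

test_that("integrate-and-fire neuron honors rheobase and adaptation", {
  prm <- ifParams()  # rest -70, threshold -40, R 200 -> rheobase 150 pA
  expect_equal(ifRheobasePa(prm), 150)
  ses <- genCurrentStepSession(prm, stepsPa = c(100, 140, 200, 400),
                               stepDurationS = 0.5)
  nsp <- lengths(ses@truthSpikeTimes)
  expect_equal(nsp[1:2], c(0L, 0L))  # below rheobase: silent
  expect_gt(nsp[3], 0)               # above rheobase: fires
  expect_true(all(diff(nsp) >= 0))

  # R = 200, rest -70, threshold -40, +100 pA: steady state -50 mV, below
  # threshold, so the noiseless neuron stays silent
  ses2 <- genCurrentStepSession(ifParams(), stepsPa = 100, stepDurationS = 1)
  expect_length(ses2@truthSpikeTimes[[1]], 0)
  # +250 pA drives the steady state to -20 mV, 20 mV above threshold
  ses3 <- genCurrentStepSession(ifParams(), stepsPa = 250, stepDurationS = 1)
  expect_gt(length(ses3@truthSpikeTimes[[1]]), 0)

  adapt <- genCurrentStepSession(ifParams(adaptIncrementPa = 30,
                                          adaptTauMs = 300),
                                 stepsPa = 300, stepDurationS = 1,
                                 dtMs = 0.05)
  isi <- diff(adapt@truthSpikeTimes[[1]])
  expect_gte(length(isi), 3)
  # ISIs non-decreasing under adaptation, up to Euler step quantization
  expect_true(all(diff(isi) >= -0.05 / 1000 - 1e-12))

  expect_error(genCurrentStepSession(prm, stepsPa = 100, stepDurationS = 0.1,
                                     dtMs = 0.3), "divide")
})

test_that("mini sweeps render the biexponential ground truth", {
  # no events, no noise: flat
  flat <- genMiniSweep(miniGroundTruth(numeric(0), numeric(0)), 1)$sweep
  expect_true(all(flat@samples == 0))

  # single 20-pA inward event: extremum within 1% of -20 pA
  one <- genMiniSweep(miniGroundTruth(0.1, 20), 0.5)$sweep
  expect_equal(min(one@samples), -20, tolerance = 0.01)
  expect_equal(max(one@samples), 0)
  out <- genMiniSweep(miniGroundTruth(0.1, 20, polarity = "outward"), 0.5)$sweep
  expect_equal(max(out@samples), 20, tolerance = 0.01)

  # Poisson event count: ~rate x duration across seeds
  counts <- vapply(1:30, function(s)
    length(genMiniTruth(100, rateHz = 3, seed = s)@eventTimesS), numeric(1))
  expect_lt(abs(mean(counts) - 300), 3 * sqrt(300) / sqrt(30) + 1)

  expect_error(genMiniSweep(miniGroundTruth(2, 20), 1), "duration")
})

test_that("LSPS generator plants classes where asked", {
  g <- lspsGrid()
  noDirect <- genLSPSDataset(g, defaultLSPSProfile(), directRadiusUm = 0,
                             nCells = 1, seed = 1)
  expect_false(any(noDirect$truth$class == "direct"))

  silent <- genLSPSDataset(g, c(L1 = 0, L23 = 0, L4 = 0, L5 = 0, L6 = 0),
                           directRadiusUm = 0, nCells = 1, seed = 1,
                           noiseSdPa = 0)
  expect_true(all(silent$truth$class == "none"))
  m <- buildInputMap(silent$recordings[[1]], "excitatory")
  expect_true(all(siteClasses(m) == "none"))
  expect_true(all(siteAmplitudes(m) == 0))

  expect_error(lspsGrid(somaRow = 40), "inside the grid")
})

test_that("LTP generator produces the planted potentiation", {
  expect_equal(ltpMagnitude(genLTPSession(-0.2, 1.0, noiseCv = 0)), 100)
  expect_equal(ltpMagnitude(genLTPSession(-0.2, 1.65, noiseCv = 0)), 165)
  mags <- vapply(1:12, function(s)
    ltpMagnitude(genLTPSession(-0.2, 1.36, noiseCv = 0.05, seed = s)),
    numeric(1))
  expect_true(all(abs(mags - 136) < 0.03 * 136))
  expect_error(genLTPSession(-0.2, 0), "potentiationFactor")
})

test_that("ground truth serializes to JSON and reloads identically", {
  dir <- withr::local_tempdir()
  tr <- genMiniTruth(10, seed = 2)
  f <- file.path(dir, "truth.json")
  writeTruthJSON(tr, f)
  back <- readTruthJSON(f)
  expect_equal(back@eventTimesS, tr@eventTimesS)
  expect_equal(back@amplitudesPa, tr@amplitudesPa)
  expect_identical(back@polarity, tr@polarity)

  odt <- genODDataset(stimProtocol(), odGroundTruth(mdShift = 0.3), 3, 2,
                      seed = 1)$truth
  f2 <- file.path(dir, "od.json")
  writeTruthJSON(odt, f2)
  back2 <- readTruthJSON(f2)
  expect_equal(back2@mdShift, odt@mdShift)
  expect_equal(back2@units, odt@units)
})
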