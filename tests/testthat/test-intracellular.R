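test_that("passive properties recover the ideal RC cell", {
  # -5 mV step, steady-state -25 pA -> Rin 200 MOhm; tau 13 ms -> Cm 65 pF
  pp <- passiveProperties(idealRCSweep(rinMohm = 200, tauMs = 13))
  expect_equal(pp@inputResistanceMohm, 200, tolerance = 1e-3)
  expect_equal(pp@timeConstantMs, 13, tolerance = 0.01)
  expect_equal(pp@capacitancePf, 65, tolerance = 0.01 * 65)

  # noisy recovery: Rin within 5% across seeds at 1 pA noise
  rins <- vapply(1:10, function(s)
    passiveProperties(idealRCSweep(noiseSdPa = 1, seed = s))@inputResistanceMohm,
    numeric(1))
  expect_true(all(abs(rins - 200) / 200 < 0.05))

  noAnn <- traceSweep(rnorm(100), 1000, "pA")
  expect_error(passiveProperties(noAnn), "annotations")
})

test_that("spike detection matches a constructed triangular spike", {
  fs <- 20000
  v <- rep(-70, 2000)
  # linear rise -70 -> +30 over 1 ms, fall +30 -> -70 over 2 ms
  rise <- seq(-70, 30, length.out = 21)
  fall <- seq(30, -70, length.out = 41)[-1]
  v[1000 + seq_along(c(rise, fall))] <- c(rise, fall)
  sw <- traceSweep(v, fs, "mV", c(0, 0.04))
  sm <- detectSpikes(sw, dvdtThreshold = 20)
  expect_length(sm@spikeTimesS, 1)
  # threshold: rising dV/dt = 100 V/s everywhere on the flank, so the first
  # criterion crossing is the first rising sample
  expect_equal(sm@thresholdMv, rise[2], tolerance = 1e-6)
  # closed-form half-width: half level = (peak + thr)/2; rise slope 5 mV per
  # sample, fall slope 2.5 mV per sample -> width = up + down crossing times
  half <- (30 + sm@thresholdMv) / 2
  upT <- (half - (-70)) / (100 * 1000) * 1000   # ms on the rising flank
  downT <- (30 - half) / (50 * 1000) * 1000     # ms on the falling flank
  riseMs <- 1; fallStartMs <- 1
  closed <- (riseMs - upT) + downT
  expect_equal(sm@halfWidthMs, closed, tolerance = 1000 / fs)  # +/- 1 sample

  sub <- traceSweep(rep(-70, 2000) + 5 * sin(1:2000 / 50), fs, "mV")
  expect_length(detectSpikes(sub)@spikeTimesS, 0)
})

test_that("detected spike times match the simulator ground truth", {
  ses <- genCurrentStepSession(ifParams(adaptIncrementPa = 20),
                               stepsPa = c(200, 350), stepDurationS = 1)
  for (k in 1:2) {
    det <- detectSpikes(ses@sweeps[[k]])@spikeTimesS
    tru <- ses@truthSpikeTimes[[k]]
    expect_length(det, length(tru))
    expect_true(all(abs(det - tru) <= 0.001))
  }
})

test_that("F-I curve is reproducible, non-decreasing, with analytic rheobase", {
  prm <- ifParams()  # rheobase 150 pA -> first spiking step is 200 pA
  ses <- genCurrentStepSession(prm, stepDurationS = 1, seed = 1)
  fi <- fiCurve(ses)
  expect_equal(fi$step_pa, seq(-100, 500, by = 50))
  expect_true(all(diff(fi$n_spikes) >= 0))
  firstActive <- fi$step_pa[which(fi$n_spikes > 0)[1]]
  expect_equal(firstActive,
               min(fi$step_pa[fi$step_pa > ifRheobasePa(prm)]))

  ses2 <- genCurrentStepSession(prm, stepDurationS = 1, seed = 1)
  expect_identical(fiCurve(ses2), fi)

  allSub <- genCurrentStepSession(prm, stepsPa = c(-100, 0, 100),
                                  stepDurationS = 0.5)
  expect_true(all(fiCurve(allSub)$n_spikes == 0))
})

test_that("SFA is the 3rd/5th inter-spike-interval ratio", {
  expect_equal(sfaIndex(cumsum(c(0, rep(100, 8))) / 1000), 1)
  isis <- c(50, 60, 70, 80, 90, 100)
  expect_equal(sfaIndex(cumsum(c(0, isis)) / 1000), 70 / 90)
  expect_error(sfaIndex((1:5) / 10), "insufficient")

  # an adapting neuron has SFA < 1 at the ~10 Hz step
  ses <- genCurrentStepSession(ifParams(adaptIncrementPa = 40,
                                        adaptTauMs = 400),
                               stepDurationS = 1)
  r <- sfaFromSession(ses)
  expect_lt(r$sfa, 1)
})

test_that("mini detection recovers planted events exactly at zero noise", {
  times <- seq(0.5, 9.5, by = 1)
  tr <- miniGroundTruth(times, 20, noiseSdPa = 0)
  sw <- genMiniSweep(tr, 10)$sweep
  ev <- detectMinis(sw)
  expect_length(ev@eventTimesS, 10)
  expect_true(all(abs(ev@amplitudesPa - 20) / 20 < 0.01))
  expect_true(all(abs(ev@eventTimesS - times) < 0.005))
  expect_equal(ev@frequencyHz, 1)

  st <- miniStats(ev)
  expect_equal(st$frequencyHz, 1)
  expect_equal(sum(st$histogram$count), 10)

  flat <- traceSweep(numeric(1000), 20000, "pA",
                     annotations = list(polarity = "inward"))
  expect_error(detectMinis(flat, thresholdSd = 0), "degenerate")
})

test_that("false positives on pure noise respect the Gaussian exceedance bound", {
  set.seed(33)
  fs <- 20000
  sw <- traceSweep(rnorm(20 * fs, 0, 4), fs, "pA",
                   annotations = list(polarity = "inward"))
  ev <- detectMinis(sw, thresholdSd = 3, smoothMs = 0)
  # an event needs at least one sample above 3 robust SD; the count of
  # suprathreshold samples bounds the event count from above
  x <- -sw@samples
  x <- x - median(x)
  nOver <- sum(x > 3 * mad(x))
  expect_lte(length(ev@eventTimesS), nOver)
  # and the suprathreshold fraction matches the Gaussian tail within MC error
  pTail <- pnorm(3, lower.tail = FALSE)
  n <- length(x)
  expect_lt(abs(nOver / n - pTail), 4 * sqrt(pTail / n) + 1e-4)
})

test_that("planted events at SNR 5 are recovered with recall/precision >= 0.9", {
  tr <- genMiniTruth(60, rateHz = 3, ampMeanPa = 20, ampSdPa = 4,
                     noiseSdPa = 4, seed = 101)
  sw <- genMiniSweep(tr, 60, seed = 102)$sweep
  ev <- detectMinis(sw)
  m <- matchEvents(tr@eventTimesS, ev@eventTimesS, tolS = 0.005)
  expect_gte(m$recall, 0.9)
  expect_gte(m$precision, 0.9)
})

test_that("detection is time-shift invariant and amplitude equivariant", {
  tr1 <- miniGroundTruth(c(1, 2.5, 4), c(15, 25, 18), noiseSdPa = 0)
  tr2 <- miniGroundTruth(c(1, 2.5, 4) + 2, c(15, 25, 18), noiseSdPa = 0)
  e1 <- detectMinis(genMiniSweep(tr1, 8)$sweep)
  e2 <- detectMinis(genMiniSweep(tr2, 8)$sweep)
  expect_equal(e2@eventTimesS - 2, e1@eventTimesS, tolerance = 1e-9)
  expect_equal(e2@amplitudesPa, e1@amplitudesPa, tolerance = 1e-9)

  sw <- genMiniSweep(tr1, 8)$sweep
  sw3 <- traceSweep(3 * sw@samples, sw@samplingRateHz, "pA",
                    sw@baselineWindowS, sw@annotations)
  e3 <- detectMinis(sw3)
  expect_equal(e3@amplitudesPa, 3 * e1@amplitudesPa, tolerance = 1e-9)
})

test_that("mini statistics agree with brute-force recomputation", {
  amps <- c(10.2, 10.7, 11.3)
  st <- miniStats(amps, durationS = 100)
  expect_equal(st$histogram$count[st$histogram$bin_lo_pa == 10], 2L)
  expect_equal(st$histogram$count[st$histogram$bin_lo_pa == 11], 1L)
  expect_equal(st$frequencyHz, 0.03)

  set.seed(7)
  amps2 <- rgamma(300, 16, 0.8)
  st2 <- miniStats(amps2, durationS = 100)
  expect_equal(st2$frequencyHz, 3)
  # histogram counts from a brute-force loop over bins
  for (i in seq_len(nrow(st2$histogram))) {
    lo <- st2$histogram$bin_lo_pa[i]
    expect_equal(st2$histogram$count[i], sum(amps2 >= lo & amps2 < lo + 1))
  }
  expect_equal(sum(st2$histogram$count), 300L)
  # ECDF steps by 1/n and ends at 1
  expect_equal(st2$ecdf$fraction, (1:300) / 300)
  expect_true(all(diff(st2$ecdf$amplitude_pa) >= 0))
  # matches stats::ecdf at every observed amplitude
  E <- ecdf(amps2)
  expect_equal(st2$ecdf$fraction, E(st2$ecdf$amplitude_pa))

  empty <- miniStats(numeric(0), durationS = 10)
  expect_equal(empty$frequencyHz, 0)
  expect_equal(nrow(empty$histogram), 0L)
})
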