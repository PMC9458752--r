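mkSiteSweep <- function(onsetMs = NULL, ampPa = -50, fs = 10000,
                        laserS = 0.05, durS = 0.2, endMs = 50,
                        noiseSdPa = 0, seed = 1) {
  set.seed(seed)
  n <- round(durS * fs)
  x <- if (noiseSdPa > 0) rnorm(n, 0, noiseSdPa) else numeric(n)
  if (!is.null(onsetMs)) {
    i1 <- round(laserS * fs) + round(onsetMs / 1000 * fs)
    i2 <- round(laserS * fs) + round(endMs / 1000 * fs)
    x[(i1 + 1):i2] <- x[(i1 + 1):i2] + ampPa
  }
  traceSweep(x, fs, "pA", c(0, laserS), list(laserOnsetS = laserS))
}

test_that("site classification follows the latency windows", {
  expect_equal(classifySite(mkSiteSweep(onsetMs = 3))$class, "direct")
  expect_equal(classifySite(mkSiteSweep(onsetMs = 12))$class, "synaptic")
  flat <- classifySite(mkSiteSweep(onsetMs = NULL))
  expect_equal(flat$class, "none")
  expect_equal(flat$amplitudePa, 0)
  sat <- mkSiteSweep(onsetMs = 12, ampPa = -5000)
  expect_equal(classifySite(sat)$class, "excluded")
  expect_error(classifySite(mkSiteSweep(12), windowsMs = c(50, 7)), "ordered")
})

test_that("site amplitude equals an independent window-mean computation", {
  sw <- mkSiteSweep(onsetMs = 12, ampPa = -40, noiseSdPa = 2, seed = 3)
  res <- classifySite(sw)
  fs <- sw@samplingRateHz
  iOn <- round(0.05 * fs)
  idx <- (iOn + round(0.007 * fs) + 1):(iOn + round(0.05 * fs))
  oracle <- mean(sw@samples[idx]) - median(sw@samples[1:iOn])
  expect_equal(res$amplitudePa, oracle, tolerance = 1e-12)

  pk <- classifySite(sw, estimator = "peak")
  oraclePk <- (sw@samples[idx] - median(sw@samples[1:iOn]))
  expect_equal(pk$amplitudePa, oraclePk[which.max(abs(oraclePk))],
               tolerance = 1e-12)
})

test_that("classification is equivariant under amplitude scaling", {
  sw <- mkSiteSweep(onsetMs = 12, ampPa = -40, noiseSdPa = 2, seed = 5)
  r1 <- classifySite(sw, thresholdPa = 6)
  sw2 <- traceSweep(3 * sw@samples, sw@samplingRateHz, "pA",
                    sw@baselineWindowS, sw@annotations)
  r2 <- classifySite(sw2, thresholdPa = 18)
  expect_equal(r2$class, r1$class)
  expect_equal(r2$amplitudePa, 3 * r1$amplitudePa, tolerance = 1e-12)
})

test_that("input maps exclude direct sites and keep the site budget", {
  sim <- genLSPSDataset(lspsGrid(), defaultLSPSProfile(),
                        directRadiusUm = 100, nCells = 1, seed = 2,
                        noiseSdPa = 0, ampCv = 0)
  m <- buildInputMap(sim$recordings[[1]], "excitatory")
  tt <- sim$truth
  expect_equal(as.vector(t(siteClasses(m))), tt$class)  # exact at zero noise
  tab <- table(factor(siteClasses(m),
                      c("direct", "synaptic", "none", "excluded")))
  expect_equal(sum(tab), 256)
  expect_true(all(is.na(siteAmplitudes(m)[siteClasses(m) == "direct"])))
  expect_true(all(siteAmplitudes(m)[siteClasses(m) == "synaptic"] <= 0))

  expect_error(buildInputMap(sim$recordings[[1]], "inhibitory"), "holding")
})

test_that("inhibitory maps carry non-negative amplitudes", {
  prof <- c(L1 = 0, L23 = 50, L4 = 0, L5 = 30, L6 = 0)
  sim <- genLSPSDataset(lspsGrid(), prof, directRadiusUm = 80, nCells = 1,
                        seed = 6, mode = "inhibitory")
  m <- buildInputMap(sim$recordings[[1]], "inhibitory")
  syn <- siteClasses(m) == "synaptic"
  expect_true(any(syn))
  expect_true(all(siteAmplitudes(m)[syn] >= 0))
})

test_that("averaging maps is the identity for one map and means across maps", {
  sim <- genLSPSDataset(lspsGrid(), defaultLSPSProfile(), nCells = 2,
                        seed = 8)
  maps <- lapply(sim$recordings, buildInputMap, mode = "excitatory")
  one <- averageMaps(maps[1])
  keep <- siteClasses(maps[[1]]) %in% c("synaptic", "none")
  expect_equal(one$meanMap[keep], siteAmplitudes(maps[[1]])[keep])
  expect_true(all(one$n[keep] == 1))
  expect_true(all(one$n[!keep] == 0))

  both <- averageMaps(maps)
  k2 <- keep & siteClasses(maps[[2]]) %in% c("synaptic", "none")
  expect_equal(both$meanMap[k2],
               (siteAmplitudes(maps[[1]])[k2] +
                  siteAmplitudes(maps[[2]])[k2]) / 2)

  inh <- genLSPSDataset(lspsGrid(), c(L1 = 0, L23 = 40, L4 = 0, L5 = 20,
                                      L6 = 0),
                        nCells = 1, seed = 9, mode = "inhibitory")
  imap <- buildInputMap(inh$recordings[[1]], "inhibitory")
  expect_error(averageMaps(list(maps[[1]], imap)), "mixed")
})

test_that("laminar profiles localize input to the planted rows", {
  g <- lspsGrid()
  uni <- matrix(-40, 16, 16)
  lp <- laminarProfile(uni, grid = g)
  expect_true(all(abs(lp@binMeanPa + 40) < 1e-12))  # every bin -40

  # nonzero only rows 3-5 (depths 150-300 um) -> only the L2/3 bin nonzero
  m <- matrix(0, 16, 16)
  m[3:5, ] <- -30
  lp2 <- laminarProfile(m, grid = g)
  nz <- which(abs(lp2@binMeanPa) > 0)
  expect_equal(lp2@binLabels[nz], "L23")
  expect_equal(lp2@combinedPa[["L23"]], -30)

  shallow <- c(L1 = 0, L23 = 100, end = 350)
  expect_error(laminarProfile(uni, layerBoundsUm = shallow, grid = g),
               "cover")
})

test_that("planted laminar profile is recovered within 10% over 10 cells", {
  sim <- genLSPSDataset(lspsGrid(), defaultLSPSProfile(),
                        directRadiusUm = 100, nCells = 10, seed = 13,
                        noiseSdPa = 2)
  maps <- lapply(sim$recordings, buildInputMap, mode = "excitatory")
  av <- averageMaps(maps)
  lp <- laminarProfile(av$meanMap, grid = lspsGrid())
  m <- setNames(lp@binMeanPa, lp@binLabels)
  expect_lt(abs(m[["L23"]] - (-50)) / 50, 0.10)
  expect_lt(abs(m[["L5"]] - (-20)) / 20, 0.10)

  agree <- vapply(seq_along(maps), function(k) {
    tt <- sim$truth[sim$truth$cell == sprintf("cell%02d", k), ]
    mean(tt$class == as.vector(t(siteClasses(maps[[k]]))))
  }, numeric(1))
  expect_gte(mean(agree), 0.95)
})
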