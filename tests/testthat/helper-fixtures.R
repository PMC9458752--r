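# Shared fixture builders. Everything is generated in code at test time.

idealRCSweep <- function(rinMohm = 200, tauMs = 13, stepMv = -5,
                         fs = 20000, onsetS = 0.05, durS = 0.2,
                         noiseSdPa = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, durS - 1 / fs, by = 1 / fs)
  iSS <- stepMv / rinMohm * 1000          # pA
  iPk <- 5 * iSS                          # transient peaks at 5x steady state
  x <- ifelse(t >= onsetS,
              iSS + (iPk - iSS) * exp(-(t - onsetS) / (tauMs / 1000)), 0)
  if (noiseSdPa > 0) x <- x + rnorm(length(x), 0, noiseSdPa)
  traceSweep(x, fs, "pA", c(0, onsetS),
             list(stepMv = stepMv, stepOnsetS = onsetS, stepOffsetS = durS))
}

# field-potential sweep: artifact, negative fiber volley, then a linear
# fEPSP segment of known slope starting slopeOffsetMs after the volley trough
fepspSweep <- function(slopeMvMs = -0.5, volleyMv = 0.2, fs = 20000,
                       stimOnsetS = 0.01, durS = 0.06, troughMs = 2,
                       slopeOffsetMs = 0.5, segMs = 1.5, scale = 1) {
  n <- round(durS * fs)
  x <- numeric(n)
  iStim <- round(stimOnsetS * fs)
  x[iStim + seq_len(round(0.0005 * fs))] <- 5  # stimulus artifact
  iTr <- iStim + round(troughMs / 1000 * fs)
  half <- round(0.0004 * fs)
  tri <- c(seq(0, -volleyMv, length.out = half + 1L),
           seq(-volleyMv, 0, length.out = half + 1L)[-1L])
  x[(iTr - half):(iTr + half)] <- tri
  i0 <- iTr + round(slopeOffsetMs / 1000 * fs)
  iSeg <- i0:(i0 + round(segMs / 1000 * fs))
  x[iSeg] <- slopeMvMs * ((iSeg - i0) / fs * 1000)
  traceSweep(scale * x, fs, "mV", c(0, stimOnsetS),
             list(stimOnsetS = stimOnsetS))
}

defaultLSPSProfile <- function() c(L1 = 0, L23 = -50, L4 = 0, L5 = -20, L6 = 0)

# greedy event matching within a time tolerance; returns recall & precision
matchEvents <- function(trueTimes, detTimes, tolS = 0.005) {
  used <- rep(FALSE, length(detTimes))
  hits <- 0L
  for (tt in trueTimes) {
    d <- abs(detTimes - tt)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tolS) {
      used[j] <- TRUE
      hits <- hits + 1L
    }
  }
  list(recall = if (length(trueTimes)) hits / length(trueTimes) else NA_real_,
       precision = if (length(detTimes)) sum(used) / length(detTimes)
       else NA_real_)
}
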