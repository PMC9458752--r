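# Seeded generators for every input modality the analysis consumes, with
# ground-truth labels for recovery tests. Each generator is a pure function of
# (arguments, seed): the global RNG state is saved and restored.

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Simulate a single-unit ocular-dominance dataset
#'
#' Generates per-trial spike counts for a population of orientation-tuned,
#' Poisson-spiking units driven through both eyes. Each unit has a preferred
#' direction shared across eyes, a von Mises-shaped rate profile, and
#' eye-specific drives drawn lognormally around the truth means; monocular
#' deprivation multiplies the contralateral (deprived) drive by
#' \code{1 - mdShift}. Spike counts are Poisson with
#' rate = baseline + eye drive x orientation tuning over the stimulus window;
#' blank trials carry the baseline rate alone.
#'
#' @param protocol A [StimProtocol-class].
#' @param truth An [ODGroundTruth-class]; population parameters.
#' @param nUnits units per mouse (>= 1).
#' @param nMice number of mice (>= 1).
#' @param seed integer seed; the generator is deterministic given it.
#' @param mouseIds optional character ids, length \code{nMice}.
#' @return A list with \code{trials}, a data.frame with columns
#'   \code{mouse_id, unit_id, eye, orientation_deg, repeat, spike_count,
#'   stim_s, trial_s} (blank rows carry \code{eye = "blank"} and \code{NA}
#'   orientation), and \code{truth}, the input [ODGroundTruth-class] with its
#'   \code{units} slot filled with the realized per-unit parameters.
#' @examples
#' sim <- genODDataset(stimProtocol(), odGroundTruth(), nUnits = 5,
#'                     nMice = 2, seed = 1)
#' head(sim$trials)
#' @export
genODDataset <- function(protocol, truth, nUnits, nMice, seed,
                         mouseIds = NULL) {
  stopifnot(is(protocol, "StimProtocol"), is(truth, "ODGroundTruth"))
  if (nUnits < 1 || nMice < 1) stop("nUnits and nMice must be >= 1")
  .withSeed(seed, {
    orients <- protocolOrientations(protocol)
    nO <- length(orients)
    reps <- protocol@repeatsPerCondition
    nTot <- nUnits * nMice
    if (is.null(mouseIds)) mouseIds <- sprintf("m%02d", seq_len(nMice))
    mouse <- rep(mouseIds, each = nUnits)
    unit <- sprintf("%s_u%03d", mouse, rep(seq_len(nUnits), nMice))

    sdl <- truth@driveSdLog
    drawDrive <- function(mu) {
      if (mu <= 0) return(rep(0, nTot))
      if (sdl == 0) return(rep(mu, nTot))
      stats::rlnorm(nTot, meanlog = log(mu) - sdl^2 / 2, sdlog = sdl)
    }
    contra <- drawDrive(truth@contraDriveHz) * (1 - truth@mdShift)
    ipsi <- drawDrive(truth@ipsiDriveHz)
    pref <- sample(orients, nTot, replace = TRUE)

    unitsDf <- data.frame(mouse_id = mouse, unit_id = unit,
                          contra_drive_hz = contra, ipsi_drive_hz = ipsi,
                          baseline_hz = truth@baselineRateHz,
                          preferred_deg = pref, stringsAsFactors = FALSE)

    # stimulus rows: unit x eye x orientation x repeat
    idx <- rep(seq_len(nTot), each = 2L * nO * reps)
    eye <- rep(rep(protocol@eyes, each = nO * reps), nTot)
    orientation <- rep(rep(rep(orients, each = reps), 2L), nTot)
    repn <- rep(seq_len(reps), 2L * nO * nTot)
    drive <- ifelse(eye == protocol@eyes[1], contra[idx], ipsi[idx])
    tuning <- exp(truth@tuningKappa *
                    (cos((orientation - pref[idx]) * pi / 180) - 1))
    rate <- truth@baselineRateHz + drive * tuning
    counts <- stats::rpois(length(rate), rate * protocol@stimDurationS)
    stim <- data.frame(mouse_id = mouse[idx], unit_id = unit[idx], eye = eye,
                       orientation_deg = orientation, repeat. = repn,
                       spike_count = counts, stringsAsFactors = FALSE)

    if (protocol@includesBlank) {
      nB <- 2L * nO * reps  # one blank preceding every stimulus trial
      bidx <- rep(seq_len(nTot), each = nB)
      blank <- data.frame(mouse_id = mouse[bidx], unit_id = unit[bidx],
                          eye = "blank", orientation_deg = NA_real_,
                          repeat. = rep(seq_len(nB), nTot),
                          spike_count = stats::rpois(nB * nTot,
                            truth@baselineRateHz * protocol@stimDurationS),
                          stringsAsFactors = FALSE)
      stim <- rbind(stim, blank)
    }
    names(stim)[names(stim) == "repeat."] <- "repeat"
    stim$stim_s <- protocol@stimDurationS
    stim$trial_s <- protocol@trialDurationS

    truth@units <- unitsDf
    list(trials = stim, truth = truth)
  })
}

#' Simulate a current-clamp step session
#'
#' Integrates an adaptive leaky integrate-and-fire neuron (forward Euler)
#' for each injected current step and renders one voltage sweep per step.
#' Spikes are rendered as stereotyped waveforms (0.3 ms rise to +35 mV, fall
#' to the reset potential) so that spike-detection code sees realistic
#' depolarizations; ground-truth spike times are stored alongside.
#'
#' @param params An [IFParams-class].
#' @param stepsPa current-step amplitudes, pA; default the standard ladder
#'   -100 to 500 pA in 50-pA increments.
#' @param stepDurationS step duration, s (default 1).
#' @param dtMs Euler time step, ms (default 0.05); must divide the step
#'   duration.
#' @param seed integer seed (only consumed when \code{noiseSdMv > 0}).
#' @param preS,postS pre-/post-step padding at rest, s (default 0.1 each).
#' @param samplingRateHz output sampling rate, Hz (default \code{1000/dtMs};
#'   must equal it, retained as an explicit argument for clarity).
#' @return A [CurrentClampSession-class] with one [TraceSweep-class] per step
#'   and ground-truth spike times.
#' @examples
#' ses <- genCurrentStepSession(ifParams(), stepsPa = c(-100, 100, 300),
#'                              stepDurationS = 0.5, seed = 1)
#' lengths(ses@truthSpikeTimes)
#' @export
genCurrentStepSession <- function(params, stepsPa = seq(-100, 500, by = 50),
                                  stepDurationS = 1, dtMs = 0.05, seed = NULL,
                                  preS = 0.1, postS = 0.1,
                                  samplingRateHz = 1000 / dtMs) {
  stopifnot(is(params, "IFParams"))
  if (!length(stepsPa)) stop("stepsPa must be non-empty")
  if (!(stepDurationS > 0)) stop("stepDurationS must be > 0")
  nStepSamp <- stepDurationS * 1000 / dtMs
  if (abs(nStepSamp - round(nStepSamp)) > 1e-9)
    stop("dtMs must divide the step duration")
  .withSeed(seed, {
    sweeps <- vector("list", length(stepsPa))
    spikes <- vector("list", length(stepsPa))
    for (k in seq_along(stepsPa)) {
      r <- .simulateIF(params, stepsPa[k], stepDurationS, dtMs, preS, postS)
      sweeps[[k]] <- traceSweep(r$v, samplingRateHz = 1000 / dtMs,
                                units = "mV", baselineWindowS = c(0, preS),
                                annotations = list(stepPa = stepsPa[k],
                                                   stepOnsetS = preS,
                                                   stepOffsetS = preS + stepDurationS))
      spikes[[k]] <- r$spikes
    }
    new("CurrentClampSession", sweeps = sweeps, stepsPa = as.numeric(stepsPa),
        stepOnsetS = preS, stepDurationS = stepDurationS, params = params,
        truthSpikeTimes = spikes)
  })
}

# Forward-Euler adaptive LIF. Units: V mV, I pA, R MOhm, C pF, taus ms;
# R*I/1000 converts pA x MOhm to mV.
.simulateIF <- function(p, stepPa, stepDurS, dtMs, preS, postS) {
  tauM <- p@resistanceMohm * p@capacitancePf / 1000  # ms
  nPre <- round(preS * 1000 / dtMs)
  nStep <- round(stepDurS * 1000 / dtMs)
  nPost <- round(postS * 1000 / dtMs)
  n <- nPre + nStep + nPost
  iExt <- c(rep(0, nPre), rep(stepPa, nStep), rep(0, nPost))
  noise <- if (p@noiseSdMv > 0)
    stats::rnorm(n, 0, p@noiseSdMv * sqrt(2 * dtMs / tauM)) else numeric(n)
  v <- numeric(n)
  vCur <- p@restMv
  w <- 0
  refractUntil <- -1
  spikes <- numeric(0)
  nRise <- max(1L, round(0.3 / dtMs))
  nFall <- max(1L, round(0.7 / dtMs))
  i <- 1L
  while (i <= n) {
    if (i <= refractUntil) {
      v[i] <- p@resetMv
      w <- w - dtMs * w / p@adaptTauMs
      i <- i + 1L
      next
    }
    v[i] <- vCur
    dv <- dtMs * (-(vCur - p@restMv) +
                    (iExt[i] - w) * p@resistanceMohm / 1000) / tauM
    vCur <- vCur + dv + (if (p@noiseSdMv > 0) noise[i] else 0)
    w <- w - dtMs * w / p@adaptTauMs
    if (vCur >= p@thresholdMv) {
      spikes <- c(spikes, (i - 1L) * dtMs / 1000)
      # stereotyped spike waveform: rise to +35 mV, fall to reset
      up <- seq(vCur, 35, length.out = nRise + 1L)[-1L]
      down <- seq(35, p@resetMv, length.out = nFall + 1L)[-1L]
      wave <- c(up, down)
      j <- i + seq_along(wave)
      keep <- j <= n
      v[j[keep]] <- wave[keep]
      w <- w + p@adaptIncrementPa
      refractUntil <- i + length(wave) +
        max(0L, round(p@refractoryMs / dtMs) - length(wave))
      i <- i + length(wave) + 1L
      vCur <- p@resetMv
      next
    }
    i <- i + 1L
  }
  list(v = v, spikes = spikes)
}

#' Rheobase of a noiseless leaky integrate-and-fire neuron
#'
#' Closed form: the smallest sustained current for which the steady-state
#' voltage reaches threshold, \eqn{I = (V_{th} - V_{rest}) / R}.
#'
#' @param params An [IFParams-class].
#' @return Rheobase current, pA.
#' @export
ifRheobasePa <- function(params) {
  (params@thresholdMv - params@restMv) / params@resistanceMohm * 1000
}

#' Generate Poisson mini-event ground truth
#'
#' Event times are homogeneous Poisson on (0, duration); amplitudes are
#' right-skewed (gamma-distributed) positive magnitudes.
#'
#' @param durationS sweep duration, s.
#' @param rateHz mean event rate, events/s (default 3).
#' @param ampMeanPa mean amplitude, pA (default 15).
#' @param ampSdPa amplitude sd, pA (default 5).
#' @param riseTauMs,decayTauMs biexponential kinetics, ms (defaults 0.5 / 5).
#' @param noiseSdPa Gaussian recording-noise sd, pA (default 2).
#' @param polarity "inward" (default) or "outward".
#' @param seed integer seed.
#' @return A [MiniGroundTruth-class].
#' @export
genMiniTruth <- function(durationS, rateHz = 3, ampMeanPa = 15, ampSdPa = 5,
                         riseTauMs = 0.5, decayTauMs = 5, noiseSdPa = 2,
                         polarity = "inward", seed = NULL) {
  stopifnot(durationS > 0, rateHz >= 0)
  .withSeed(seed, {
    nEv <- stats::rpois(1, rateHz * durationS)
    times <- sort(stats::runif(nEv, 0, durationS))
    times <- times[!duplicated(times)]
    shape <- (ampMeanPa / ampSdPa)^2
    amps <- if (length(times))
      stats::rgamma(length(times), shape = shape,
                    rate = shape / ampMeanPa) else numeric(0)
    miniGroundTruth(times, pmax(amps, 0.1), riseTauMs = riseTauMs,
                    decayTauMs = decayTauMs, noiseSdPa = noiseSdPa,
                    polarity = polarity)
  })
}

# Unit-peak biexponential kernel sampled at dt (s); support truncated where
# the decay falls below 1e-4 of the peak.
.biexpKernel <- function(riseTauMs, decayTauMs, samplingRateHz) {
  tr <- riseTauMs / 1000
  td <- decayTauMs / 1000
  tPeak <- tr * td / (td - tr) * log(td / tr)
  tEnd <- tPeak + td * log(1e4)
  t <- seq(0, tEnd, by = 1 / samplingRateHz)
  g <- exp(-t / td) - exp(-t / tr)
  g / (exp(-tPeak / td) - exp(-tPeak / tr))
}

#' Render a miniature-PSC sweep from ground truth
#'
#' The sweep is the sum of unit-peak biexponential kernels scaled to each
#' event's amplitude, at the truth event times, plus Gaussian noise; inward
#' polarity deflects negative.
#'
#' @param truth A [MiniGroundTruth-class].
#' @param durationS sweep duration, s (all event times must fall inside).
#' @param samplingRateHz sampling rate, Hz (default 20000).
#' @param seed integer seed for the noise.
#' @return A list with \code{sweep} (a [TraceSweep-class] in pA, annotation
#'   \code{polarity}) and \code{truth} (the input, returned unchanged).
#' @examples
#' tr <- miniGroundTruth(c(0.1, 0.25), 20)
#' sw <- genMiniSweep(tr, durationS = 0.5, seed = 1)$sweep
#' range(sw@samples)
#' @export
genMiniSweep <- function(truth, durationS, samplingRateHz = 20000,
                         seed = NULL) {
  stopifnot(is(truth, "MiniGroundTruth"))
  if (!(durationS > 0) || !(samplingRateHz > 0))
    stop("durationS and samplingRateHz must be > 0")
  if (length(truth@eventTimesS) && max(truth@eventTimesS) >= durationS)
    stop("event time at or beyond sweep duration")
  .withSeed(seed, {
    n <- round(durationS * samplingRateHz)
    x <- numeric(n)
    if (length(truth@eventTimesS)) {
      kern <- .biexpKernel(truth@riseTauMs, truth@decayTauMs, samplingRateHz)
      for (k in seq_along(truth@eventTimesS)) {
        i0 <- floor(truth@eventTimesS[k] * samplingRateHz) + 1L
        j <- i0:min(n, i0 + length(kern) - 1L)
        x[j] <- x[j] + truth@amplitudesPa[k] * kern[seq_along(j)]
      }
    }
    if (truth@polarity == "inward") x <- -x
    if (truth@noiseSdPa > 0) x <- x + stats::rnorm(n, 0, truth@noiseSdPa)
    sweep <- traceSweep(x, samplingRateHz, units = "pA",
                        baselineWindowS = c(0, durationS),
                        annotations = list(polarity = truth@polarity))
    list(sweep = sweep, truth = truth)
  })
}

#' Default cortical layer bounds
#'
#' Approximate mouse V1 laminar boundaries, micrometres below the pia:
#' L1 0-100, L2/3 100-350, L4 350-450, L5 450-650, L6 650-900, plus a
#' white-matter bin 900-1200 so the default 16 x 75 um grid (deepest row at
#' 1125 um) is fully covered.
#'
#' @return Named numeric vector of bin edges (um); names label the layer
#'   starting at each edge except the last.
#' @export
defaultLayerBounds <- function() {
  c(L1 = 0, L23 = 100, L4 = 350, L5 = 450, L6 = 650, wm = 900, end = 1200)
}

.layerOfDepth <- function(depthUm, boundsUm = defaultLayerBounds()) {
  lev <- names(boundsUm)[-length(boundsUm)]
  idx <- findInterval(depthUm, boundsUm, rightmost.closed = TRUE)
  idx[idx < 1 | idx > length(lev)] <- NA_integer_
  lev[idx]
}

#' Simulate an LSPS mapping dataset
#'
#' Generates per-site voltage-clamp sweeps for \code{nCells} cells on a
#' stimulation grid with layer-structured connectivity. Each site whose
#' layer-mean amplitude is nonzero produces a synaptic current: onset jittered
#' shortly after the close of the direct window, a plateau at the layer mean
#' (times a per-site lognormal factor) held through the synaptic analysis
#' window, then an exponential decay. Sites within \code{directRadiusUm} of
#' the soma additionally receive a large short-latency direct response.
#' Ground truth records every site's class and planted amplitude.
#'
#' @param grid An [LSPSGrid-class].
#' @param layerProfilePa named numeric of per-layer mean synaptic amplitudes
#'   (pA, signed; inward negative), names matching the layers of
#'   \code{layerBoundsUm}. Layers absent from the profile are an error.
#' @param directRadiusUm radius around the soma producing direct responses.
#' @param nCells number of cells to simulate (>= 1).
#' @param seed integer seed.
#' @param mode "excitatory" (holding -70 mV) or "inhibitory" (0 mV); must
#'   agree with the sign of the nonzero profile entries.
#' @param layerBoundsUm layer bin edges, um (default [defaultLayerBounds()]).
#' @param ampCv per-site lognormal coefficient of variation of the synaptic
#'   amplitude (default 0.1).
#' @param noiseSdPa recording-noise sd, pA (default 2).
#' @param directAmpPa direct-response magnitude, pA (default 400).
#' @param samplingRateHz sweep sampling rate (default 10000).
#' @param laserOnsetS laser onset within each sweep, s (default 0.05).
#' @param sweepDurationS sweep length, s (default 0.2).
#' @param synapticWindowMs (direct end, synaptic end) latencies, ms,
#'   default c(7, 50); onsets are drawn uniformly over the first 3 ms of the
#'   synaptic window.
#' @return A list with \code{recordings}, a list of [LSPSRecording-class],
#'   and \code{truth}, a data.frame with columns \code{cell, row, col, class,
#'   amplitude_pa}.
#' @export
genLSPSDataset <- function(grid, layerProfilePa, directRadiusUm = 100,
                           nCells = 1L, seed = NULL,
                           mode = c("excitatory", "inhibitory"),
                           layerBoundsUm = defaultLayerBounds(),
                           ampCv = 0.1, noiseSdPa = 2, directAmpPa = 400,
                           samplingRateHz = 10000, laserOnsetS = 0.05,
                           sweepDurationS = 0.2,
                           synapticWindowMs = c(7, 50)) {
  stopifnot(is(grid, "LSPSGrid"))
  mode <- match.arg(mode)
  if (nCells < 1) stop("nCells must be >= 1")
  layers <- names(layerBoundsUm)[-length(layerBoundsUm)]
  depths <- gridRowDepthsUm(grid)
  rowLayer <- .layerOfDepth(depths, layerBoundsUm)
  # cortical layers spanned by the grid must be in the profile; the
  # white-matter bin (and rows beyond the bounds) default to no input
  need <- setdiff(unique(rowLayer[!is.na(rowLayer)]), "wm")
  if (!all(need %in% names(layerProfilePa)))
    stop("layerProfilePa must cover all layers spanned by the grid: missing ",
         paste(setdiff(need, names(layerProfilePa)), collapse = ", "))
  sgn <- if (mode == "excitatory") -1 else 1
  if (any(sign(layerProfilePa[layerProfilePa != 0]) != sgn))
    stop("profile sign must match mode (excitatory negative, inhibitory positive)")
  .withSeed(seed, {
    nSite <- grid@rows * grid@cols
    siteRow <- rep(seq_len(grid@rows), times = grid@cols)
    siteCol <- rep(seq_len(grid@cols), each = grid@rows)
    # row-major site index: (row-1)*cols + col
    ord <- order((siteRow - 1L) * grid@cols + siteCol)
    siteRow <- siteRow[ord]; siteCol <- siteCol[ord]
    distUm <- sqrt((siteRow - grid@somaRow)^2 + (siteCol - grid@somaCol)^2) *
      grid@spacingUm
    n <- round(sweepDurationS * samplingRateHz)
    iLaser <- round(laserOnsetS * samplingRateHz)
    tDms <- synapticWindowMs[1]; tSms <- synapticWindowMs[2]
    recs <- vector("list", nCells)
    truthList <- vector("list", nCells)
    for (cc in seq_len(nCells)) {
      sweeps <- vector("list", nSite)
      cls <- character(nSite)
      amp <- numeric(nSite)
      for (s in seq_len(nSite)) {
        x <- if (noiseSdPa > 0) stats::rnorm(n, 0, noiseSdPa) else numeric(n)
        lay <- rowLayer[siteRow[s]]
        mu <- if (is.na(lay) || !lay %in% names(layerProfilePa)) 0
        else layerProfilePa[[lay]]
        isDirect <- distUm[s] <= directRadiusUm
        if (!is.na(mu) && mu != 0) {
          a <- if (ampCv > 0)
            mu * stats::rlnorm(1, -log(1 + ampCv^2) / 2, sqrt(log(1 + ampCv^2)))
          else mu
          onMs <- stats::runif(1, tDms, tDms + 3)
          i1 <- iLaser + round(onMs / 1000 * samplingRateHz)
          i2 <- iLaser + round(tSms / 1000 * samplingRateHz)
          j <- (i1 + 1L):min(n, i2)
          x[j] <- x[j] + a
          # exponential tail after the analysis window (tau 20 ms)
          if (i2 < n) {
            jt <- (i2 + 1L):n
            x[jt] <- x[jt] + a * exp(-(jt - i2) / (0.02 * samplingRateHz))
          }
          cls[s] <- "synaptic"; amp[s] <- a
        } else {
          cls[s] <- "none"; amp[s] <- 0
        }
        if (isDirect) {
          onMs <- stats::runif(1, 0.5, 3)
          i1 <- iLaser + round(onMs / 1000 * samplingRateHz)
          j <- (i1 + 1L):min(n, i1 + round(0.03 * samplingRateHz))
          x[j] <- x[j] + sgn * directAmpPa * exp(-(seq_along(j)) /
                                                   (0.005 * samplingRateHz))
          cls[s] <- "direct"
        }
        sweeps[[s]] <- traceSweep(x, samplingRateHz, units = "pA",
                                  baselineWindowS = c(0, laserOnsetS),
                                  annotations = list(laserOnsetS = laserOnsetS))
      }
      recs[[cc]] <- new("LSPSRecording", grid = grid,
                        holdingMv = if (mode == "excitatory") -70 else 0,
                        sweeps = sweeps, cellId = sprintf("cell%02d", cc),
                        group = "sim")
      truthList[[cc]] <- data.frame(cell = sprintf("cell%02d", cc),
                                    row = siteRow, col = siteCol,
                                    class = cls, amplitude_pa = amp,
                                    stringsAsFactors = FALSE)
    }
    list(recordings = recs, truth = do.call(rbind, truthList))
  })
}

#' Simulate an LTP slope time course
#'
#' Slopes are sampled at a fixed inter-sweep interval (default 20 s, the
#' 0.05-Hz baseline stimulation rate): the baseline slope before induction,
#' baseline x \code{potentiationFactor} after, with multiplicative Gaussian
#' noise of coefficient of variation \code{noiseCv}.
#'
#' @param baselineSlopeMvMs baseline fEPSP slope, mV/ms.
#' @param potentiationFactor post/pre slope ratio (> 0); 1 = no potentiation.
#' @param noiseCv multiplicative noise CV (>= 0).
#' @param intervalS inter-sweep interval, s (default 20).
#' @param preMin baseline duration, min (default 10).
#' @param postMin post-induction duration, min (default 60).
#' @param seed integer seed.
#' @return An [LTPTimecourse-class]; induction occurs at \code{preMin} min.
#' @examples
#' tc <- genLTPSession(-0.2, 1.65, noiseCv = 0, seed = 1)
#' ltpMagnitude(tc)
#' @export
genLTPSession <- function(baselineSlopeMvMs, potentiationFactor,
                          noiseCv = 0.05, intervalS = 20, preMin = 10,
                          postMin = 60, seed = NULL) {
  if (!(potentiationFactor > 0)) stop("potentiationFactor must be > 0")
  if (noiseCv < 0) stop("noiseCv must be >= 0")
  .withSeed(seed, {
    induction <- preMin * 60
    times <- seq(intervalS, (preMin + postMin) * 60, by = intervalS)
    fac <- ifelse(times > induction, potentiationFactor, 1)
    noise <- if (noiseCv > 0)
      pmax(1 + stats::rnorm(length(times), 0, noiseCv), 0.05) else 1
    ltpTimecourse(times, baselineSlopeMvMs * fac * noise,
                  inductionTimeS = induction)
  })
}
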