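# Intracellular analyses: passive membrane properties from -5 mV voltage
# steps, spike detection and intrinsic-excitability metrics, spike-frequency
# adaptation, and miniature-PSC detection and statistics.

#' Passive membrane properties
#'
#' @slot inputResistanceMohm input resistance, MOhm.
#' @slot capacitancePf membrane capacitance, pF.
#' @slot timeConstantMs membrane time constant, ms.
#' @export
setClass("PassiveProps", representation(
  inputResistanceMohm = "numeric", capacitancePf = "numeric",
  timeConstantMs = "numeric"
))

setValidity("PassiveProps", function(object) {
  if (object@inputResistanceMohm <= 0 || object@capacitancePf <= 0 ||
      object@timeConstantMs <= 0) "all properties must be > 0" else TRUE
})

setMethod("show", "PassiveProps", function(object) {
  cat(sprintf("PassiveProps: Rin = %.1f MOhm, Cm = %.1f pF, tau = %.2f ms\n",
              object@inputResistanceMohm, object@capacitancePf,
              object@timeConstantMs))
})

#' Spike metrics for one sweep
#'
#' @slot spikeTimesS spike times, s (upward 0-mV crossings).
#' @slot thresholdMv per-spike threshold voltage (first dV/dt criterion
#'   crossing before the peak), mV.
#' @slot halfWidthMs per-spike width at half of (peak - threshold), ms.
#' @export
setClass("SpikeMetrics", representation(
  spikeTimesS = "numeric", thresholdMv = "numeric", halfWidthMs = "numeric"
))

setMethod("show", "SpikeMetrics", function(object) {
  cat(sprintf("SpikeMetrics: %d spikes", length(object@spikeTimesS)))
  if (length(object@spikeTimesS))
    cat(sprintf("; mean threshold %.1f mV, mean half-width %.2f ms",
                mean(object@thresholdMv, na.rm = TRUE),
                mean(object@halfWidthMs, na.rm = TRUE)))
  cat("\n")
})

#' Miniature-event table
#'
#' @slot eventTimesS event times, s.
#' @slot amplitudesPa positive event amplitudes, pA.
#' @slot interEventIntervalsS inter-event intervals, s.
#' @slot frequencyHz events per second over the analysed duration.
#' @slot polarity "inward" or "outward".
#' @slot durationS analysed duration, s.
#' @export
setClass("MiniEventTable", representation(
  eventTimesS = "numeric", amplitudesPa = "numeric",
  interEventIntervalsS = "numeric", frequencyHz = "numeric",
  polarity = "character", durationS = "numeric"
))

setMethod("show", "MiniEventTable", function(object) {
  cat(sprintf("MiniEventTable: %d %s events in %.1f s (%.2f Hz)",
              length(object@eventTimesS), object@polarity, object@durationS,
              object@frequencyHz))
  if (length(object@amplitudesPa))
    cat(sprintf("; mean amplitude %.1f pA", mean(object@amplitudesPa)))
  cat("\n")
})

# Fits y = yInf + a * exp(-t / tau): log-linear fit over the informative part
# of the decay (above 2% of the initial deviation, i.e. ~4 time constants) to
# start nls; the log-linear estimate stands when nls fails to converge, which
# happens by construction on zero-residual (noiseless) data.
.fitExpDecay <- function(t, y, yInf = NULL) {
  if (is.null(yInf)) yInf <- mean(y[t >= stats::quantile(t, 0.8)])
  d <- y - yInf
  s <- if (d[1] >= 0) 1 else -1
  pos <- which(s * d > max(s * d) * 0.02)
  if (length(pos) < 3L)
    stop("estimation failure: transient too small to fit")
  lf <- stats::lm(log(s * d[pos]) ~ t[pos])
  tau0 <- -1 / stats::coef(lf)[2]
  a0 <- s * exp(stats::coef(lf)[1])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(t) / 5
  fit <- tryCatch(
    stats::nls(y ~ yi + a * exp(-t / tau),
               start = list(yi = yInf, a = a0, tau = tau0)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    co <- stats::coef(fit)
    list(tau = unname(co["tau"]), a = unname(co["a"]), yInf = unname(co["yi"]))
  } else {
    list(tau = unname(tau0), a = unname(a0), yInf = yInf)
  }
}

#' Passive properties from a -5 mV voltage step
#'
#' From the current response to a small hyperpolarizing voltage step:
#' input resistance Rin = step / steady-state current change (steady state =
#' mean over the final 20% of the step), membrane time constant tau from a
#' single-exponential fit of the capacitive-transient decay, and capacitance
#' Cm = tau / Rin.
#'
#' @param sweep a voltage-clamp [TraceSweep-class] in pA with annotations
#'   \code{stepMv}, \code{stepOnsetS}, \code{stepOffsetS}.
#' @param steadyFraction final fraction of the step treated as steady state
#'   (default 0.2).
#' @return A [PassiveProps-class].
#' @examples
#' # ideal RC: -5 mV step, Rin 200 MOhm, tau 13 ms -> Cm 65 pF
#' fs <- 20000; t <- seq(0, 0.2 - 1 / fs, by = 1 / fs)
#' iSS <- -5 / 200 * 1000
#' i <- ifelse(t >= 0.05, iSS + (4 * iSS) * exp(-(t - 0.05) / 0.013), 0)
#' sw <- traceSweep(i, fs, "pA", c(0, 0.05),
#'                  list(stepMv = -5, stepOnsetS = 0.05, stepOffsetS = 0.2))
#' passiveProperties(sw)
#' @export
passiveProperties <- function(sweep, steadyFraction = 0.2) {
  stopifnot(is(sweep, "TraceSweep"))
  ann <- sweep@annotations
  if (is.null(ann$stepMv) || is.null(ann$stepOnsetS))
    stop("step annotations (stepMv, stepOnsetS) required")
  fs <- sweep@samplingRateHz
  x <- sweep@samples
  i0 <- round(ann$stepOnsetS * fs)
  i1 <- if (!is.null(ann$stepOffsetS)) round(ann$stepOffsetS * fs)
  else length(x)
  i1 <- min(i1, length(x))
  base <- mean(x[seq_len(max(1L, i0 - 1L))])
  ssIdx <- (i1 - round(steadyFraction * (i1 - i0))):i1
  dISS <- mean(x[ssIdx]) - base
  if (dISS == 0) stop("no steady-state current change: Rin undefined")
  rin <- ann$stepMv / dISS * 1000  # mV/pA = GOhm; x1000 -> MOhm
  # capacitive transient: decay from the post-onset extremum to steady state
  trans <- (i0 + 1L):i1
  pk <- trans[which.max(abs(x[trans] - (base + dISS)))]
  fitIdx <- pk:i1
  tMs <- (fitIdx - pk) / fs * 1000
  fit <- .fitExpDecay(tMs, x[fitIdx], yInf = base + dISS)
  if (!is.finite(fit$tau) || fit$tau <= 0)
    stop("estimation failure: transient fit returned non-positive tau")
  new("PassiveProps", inputResistanceMohm = rin,
      capacitancePf = fit$tau / rin * 1000, timeConstantMs = fit$tau)
}

#' Detect action potentials in a current-clamp sweep
#'
#' A spike is an upward crossing of 0 mV; crossings closer than
#' \code{mergeMs} are treated as one spike. Per spike, the threshold is the
#' voltage at the first sample (scanning forward from shortly before the
#' crossing) where dV/dt reaches the criterion, and the half-width is the
#' width of the spike at half of (peak - threshold), by linear interpolation
#' on the rising and falling flanks.
#'
#' @param sweep a current-clamp [TraceSweep-class] in mV.
#' @param dvdtThreshold threshold criterion, V/s (default 20).
#' @param mergeMs minimum spike separation, ms (default 2).
#' @param lookbackMs how far before the 0-mV crossing to search for the
#'   threshold, ms (default 5).
#' @return A [SpikeMetrics-class]; zero spikes is an empty result, not an
#'   error.
#' @export
detectSpikes <- function(sweep, dvdtThreshold = 20, mergeMs = 2,
                         lookbackMs = 5) {
  stopifnot(is(sweep, "TraceSweep"))
  fs <- sweep@samplingRateHz
  v <- sweep@samples
  up <- which(v[-1L] >= 0 & v[-length(v)] < 0) + 1L
  if (length(up) > 1L) up <- up[c(TRUE, diff(up) > mergeMs / 1000 * fs)]
  if (!length(up))
    return(new("SpikeMetrics", spikeTimesS = numeric(0),
               thresholdMv = numeric(0), halfWidthMs = numeric(0)))
  dvdt <- c(NA_real_, diff(v)) * fs / 1000  # V/s
  thr <- hw <- rep(NA_real_, length(up))
  for (k in seq_along(up)) {
    i <- up[k]
    segEnd <- if (k < length(up)) up[k + 1L] - 1L else length(v)
    seg <- i:min(segEnd, i + round(0.005 * fs))
    pk <- seg[which.max(v[seg])]
    lb <- max(2L, i - round(lookbackMs / 1000 * fs))
    rise <- lb:pk
    cross <- rise[which(dvdt[rise] >= dvdtThreshold)[1]]
    if (!is.na(cross)) thr[k] <- v[cross]
    if (!is.na(thr[k]) && v[pk] > thr[k]) {
      half <- thr[k] + (v[pk] - thr[k]) / 2
      # rising flank: last sub-half sample before the peak
      iL <- rev(lb:pk)[which(v[rev(lb:pk)] < half)[1]]
      tL <- if (!is.na(iL) && iL < pk)
        iL + (half - v[iL]) / (v[iL + 1L] - v[iL]) else NA_real_
      # falling flank: first sub-half sample after the peak
      post <- pk:min(segEnd, pk + round(0.01 * fs))
      iR <- post[which(v[post] < half)[1]]
      tR <- if (!is.na(iR) && iR > pk)
        (iR - 1L) + (v[iR - 1L] - half) / (v[iR - 1L] - v[iR]) else NA_real_
      if (!is.na(tL) && !is.na(tR)) hw[k] <- (tR - tL) * 1000 / fs
    }
  }
  new("SpikeMetrics", spikeTimesS = (up - 1L) / fs, thresholdMv = thr,
      halfWidthMs = hw)
}

#' F-I curve: spike counts per current step
#'
#' Counts detected spikes within the step window of every sweep of a
#' current-clamp session.
#'
#' @param session a [CurrentClampSession-class].
#' @param ... passed to [detectSpikes()].
#' @return data.frame with columns \code{step_pa}, \code{n_spikes}.
#' @examples
#' ses <- genCurrentStepSession(ifParams(), stepsPa = c(0, 200, 400),
#'                              stepDurationS = 0.3)
#' fiCurve(ses)
#' @export
fiCurve <- function(session, ...) {
  stopifnot(is(session, "CurrentClampSession"))
  t0 <- session@stepOnsetS
  t1 <- t0 + session@stepDurationS
  n <- vapply(session@sweeps, function(sw) {
    st <- detectSpikes(sw, ...)@spikeTimesS
    sum(st >= t0 & st < t1)
  }, integer(1))
  data.frame(step_pa = session@stepsPa, n_spikes = n)
}

#' Spike-frequency adaptation index
#'
#' The ratio of the 3rd to the 5th inter-spike interval during a current step
#' evoking roughly 10 Hz firing. Values below 1 indicate adaptation
#' (lengthening intervals).
#'
#' @param spikeTimesS spike times within one step, s; at least 7 spikes are
#'   required so the 5th interval exists.
#' @return ISI3 / ISI5, dimensionless.
#' @examples
#' sfaIndex(cumsum(c(0, 50, 60, 70, 80, 90, 100)) / 1000)  # 70/90
#' @export
sfaIndex <- function(spikeTimesS) {
  if (length(spikeTimesS) < 7L)
    stop("insufficient spikes: >= 7 needed for the 5th inter-spike interval")
  isi <- diff(sort(spikeTimesS))
  isi[3] / isi[5]
}

#' Select the SFA step from a session
#'
#' Picks the smallest current step evoking at least \code{minSpikes} spikes
#' over the step (about 10 Hz for a 1-s step) and returns its SFA index.
#'
#' @param session a [CurrentClampSession-class].
#' @param minSpikes minimum spike count for the scored step (default 8).
#' @param ... passed to [detectSpikes()].
#' @return list with \code{step_pa} and \code{sfa}.
#' @export
sfaFromSession <- function(session, minSpikes = 8L, ...) {
  stopifnot(is(session, "CurrentClampSession"))
  t0 <- session@stepOnsetS; t1 <- t0 + session@stepDurationS
  ord <- order(session@stepsPa)
  for (k in ord) {
    st <- detectSpikes(session@sweeps[[k]], ...)@spikeTimesS
    st <- st[st >= t0 & st < t1]
    if (length(st) >= max(minSpikes, 7L))
      return(list(step_pa = session@stepsPa[k], sfa = sfaIndex(st)))
  }
  stop("insufficient spikes: no step evoked >= ", minSpikes, " spikes")
}

#' Detect miniature postsynaptic currents
#'
#' Amplitude-threshold detection on the polarity-rectified,
#' baseline-subtracted current trace: the trace is median-baselined, flipped
#' so events are positive, boxcar-smoothed for detection, and scanned for
#' excursions above threshold; excursions separated by less than
#' \code{minIntervalMs} merge into one event. The threshold is
#' \code{thresholdSd} x the robust RMS (1.4826 MAD) of the raw rectified
#' trace. Event amplitude is the unsmoothed extremum within the excursion
#' minus the baseline; event time is the extremum time.
#'
#' @param sweep a voltage-clamp [TraceSweep-class] in pA.
#' @param thresholdSd threshold in multiples of the baseline RMS (default 3).
#' @param minIntervalMs merge window, ms (default 5).
#' @param polarity "inward" or "outward"; defaults to the sweep's
#'   \code{polarity} annotation.
#' @param smoothMs detection smoothing boxcar, ms (default 0.5; 0 disables).
#' @return A [MiniEventTable-class].
#' @examples
#' tr <- genMiniTruth(20, rateHz = 2, noiseSdPa = 2, seed = 1)
#' sw <- genMiniSweep(tr, 20, seed = 2)$sweep
#' detectMinis(sw)
#' @export
detectMinis <- function(sweep, thresholdSd = 3, minIntervalMs = 5,
                        polarity = NULL, smoothMs = 0.5) {
  stopifnot(is(sweep, "TraceSweep"))
  if (is.null(polarity)) polarity <- sweep@annotations$polarity
  if (is.null(polarity) || !polarity %in% c("inward", "outward"))
    stop("polarity must be 'inward' or 'outward'")
  fs <- sweep@samplingRateHz
  x <- sweep@samples
  if (polarity == "inward") x <- -x
  x <- x - stats::median(x)
  rms <- stats::mad(x)
  thrPa <- thresholdSd * rms
  if (thrPa == 0 && thresholdSd == 0)
    stop("degenerate threshold: baseline RMS and threshold are both zero")
  det <- if (smoothMs > 0) .boxcarSmooth(x, max(1L, round(smoothMs / 1000 * fs)))
  else x
  overIdx <- which(det > thrPa)
  dur <- length(x) / fs
  if (!length(overIdx))
    return(new("MiniEventTable", eventTimesS = numeric(0),
               amplitudesPa = numeric(0), interEventIntervalsS = numeric(0),
               frequencyHz = 0, polarity = polarity, durationS = dur))
  gap <- minIntervalMs / 1000 * fs
  newEvent <- c(TRUE, diff(overIdx) > gap)
  eventId <- cumsum(newEvent)
  times <- amps <- numeric(max(eventId))
  nb <- max(1L, round(0.00025 * fs))  # +/- 0.25 ms around the detection peak
  for (e in seq_len(max(eventId))) {
    idx <- overIdx[eventId == e]
    span <- idx[1]:idx[length(idx)]
    pkDet <- span[which.max(det[span])]
    win <- max(1L, pkDet - nb):min(length(x), pkDet + nb)
    pk <- win[which.max(x[win])]
    times[e] <- (pk - 1L) / fs
    amps[e] <- x[pk]
  }
  new("MiniEventTable", eventTimesS = times, amplitudesPa = amps,
      interEventIntervalsS = diff(times), frequencyHz = length(times) / dur,
      polarity = polarity, durationS = dur)
}

#' Mini-event statistics
#'
#' 1-pA amplitude histogram, empirical cumulative distribution, mean
#' amplitude, and frequency = event count / analysed duration.
#'
#' @param events a [MiniEventTable-class], or a numeric vector of amplitudes.
#' @param durationS analysed duration, s (taken from the event table when
#'   omitted).
#' @param binPa histogram bin width, pA (default 1).
#' @return A list with \code{histogram} (data.frame \code{bin_lo_pa,
#'   bin_hi_pa, count}; bins \[lo, hi)), \code{ecdf} (data.frame
#'   \code{amplitude_pa, fraction}), \code{meanAmplitudePa},
#'   \code{frequencyHz}, \code{n}. An empty table yields zero frequency and
#'   an empty histogram.
#' @examples
#' miniStats(c(10.2, 10.7, 11.3), durationS = 100)
#' @export
miniStats <- function(events, durationS = NULL, binPa = 1) {
  amps <- if (is(events, "MiniEventTable")) events@amplitudesPa
  else as.numeric(events)
  if (is.null(durationS)) {
    if (!is(events, "MiniEventTable"))
      stop("durationS required when events is a plain vector")
    durationS <- events@durationS
  }
  if (!(durationS > 0)) stop("durationS must be > 0")
  n <- length(amps)
  if (!n) {
    return(list(histogram = data.frame(bin_lo_pa = numeric(0),
                                       bin_hi_pa = numeric(0),
                                       count = integer(0)),
                ecdf = data.frame(amplitude_pa = numeric(0),
                                  fraction = numeric(0)),
                meanAmplitudePa = NaN, frequencyHz = 0, n = 0L))
  }
  lo <- floor(min(amps) / binPa) * binPa
  hi <- floor(max(amps) / binPa) * binPa + binPa
  edges <- seq(lo, hi, by = binPa)
  counts <- as.integer(table(cut(amps, edges, right = FALSE,
                                 include.lowest = FALSE)))
  srt <- sort(amps)
  list(histogram = data.frame(bin_lo_pa = edges[-length(edges)],
                              bin_hi_pa = edges[-1], count = counts),
       ecdf = data.frame(amplitude_pa = srt,
                         fraction = seq_len(n) / n),
       meanAmplitudePa = mean(amps), frequencyHz = n / durationS, n = n)
}
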