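# Field-potential scoring: fiber volley, the 1-ms fEPSP slope, input-output
# curves, paired-pulse ratios, theta-burst induction timing, and the LTP
# magnitude over the final window of a normalized slope time course.

#' fEPSP measurement for one sweep
#'
#' @slot fiberVolleyMv fiber-volley amplitude (baseline minus trough,
#'   positive magnitude), mV.
#' @slot slopeMvMs fEPSP slope over the 1-ms window after the fiber volley,
#'   mV/ms.
#' @slot stimulusUa stimulus intensity, uA (NA when not annotated).
#' @slot sweepTimeS sweep time stamp, s (NA when not annotated).
#' @slot detected logical; FALSE for a null measure (flat sweep).
#' @export
setClass("FepspMeasure", representation(
  fiberVolleyMv = "numeric", slopeMvMs = "numeric", stimulusUa = "numeric",
  sweepTimeS = "numeric", detected = "logical"
))

setMethod("show", "FepspMeasure", function(object) {
  if (!object@detected) cat("FepspMeasure: no detectable fEPSP\n")
  else cat(sprintf("FepspMeasure: fiber volley %.3f mV, slope %.3f mV/ms\n",
                   object@fiberVolleyMv, object@slopeMvMs))
})

#' Theta-burst induction protocol
#'
#' @slot burstHz intra-burst pulse frequency, Hz (100).
#' @slot pulsesPerBurst pulses per burst (4).
#' @slot burstRateHz burst rate within a train, Hz (5).
#' @slot trainDurationS train duration, s (2).
#' @slot trainCount number of trains (5).
#' @slot interTrainIntervalS interval between train onsets, s (10).
#' @export
setClass("InductionProtocol", representation(
  burstHz = "numeric", pulsesPerBurst = "integer", burstRateHz = "numeric",
  trainDurationS = "numeric", trainCount = "integer",
  interTrainIntervalS = "numeric"
))

setValidity("InductionProtocol", function(object) {
  msg <- character()
  if (object@pulsesPerBurst < 1L || object@trainCount < 1L)
    msg <- c(msg, "pulse and train counts must be >= 1")
  if (object@burstHz <= object@burstRateHz)
    msg <- c(msg, "intra-burst frequency must exceed the burst rate")
  if (length(msg)) msg else TRUE
})

setMethod("show", "InductionProtocol", function(object) {
  nb <- floor(object@trainDurationS * object@burstRateHz)
  cat(sprintf(paste0("InductionProtocol: %d trains of %g s at %g Hz bursts ",
                     "(%d x %g Hz pulses), %g s apart; %d pulses total\n"),
              object@trainCount, object@trainDurationS, object@burstRateHz,
              object@pulsesPerBurst, object@burstHz,
              object@interTrainIntervalS,
              object@trainCount * nb * object@pulsesPerBurst))
})

#' Construct a theta-burst protocol
#'
#' Defaults give the standard induction: a 2-s train of 5-Hz bursts, each
#' burst four pulses at 100 Hz, repeated five times at 10-s intervals
#' (200 pulses in all).
#'
#' @param burstHz intra-burst frequency, Hz (default 100).
#' @param pulsesPerBurst pulses per burst (default 4).
#' @param burstRateHz burst rate, Hz (default 5).
#' @param trainDurationS train duration, s (default 2).
#' @param trainCount trains (default 5).
#' @param interTrainIntervalS train-onset interval, s (default 10).
#' @return An [InductionProtocol-class].
#' @export
inductionProtocol <- function(burstHz = 100, pulsesPerBurst = 4L,
                              burstRateHz = 5, trainDurationS = 2,
                              trainCount = 5L, interTrainIntervalS = 10) {
  new("InductionProtocol", burstHz = burstHz,
      pulsesPerBurst = as.integer(pulsesPerBurst), burstRateHz = burstRateHz,
      trainDurationS = trainDurationS, trainCount = as.integer(trainCount),
      interTrainIntervalS = interTrainIntervalS)
}

#' Measure fiber volley and fEPSP slope on one sweep
#'
#' After blanking the stimulus artifact, the fiber volley is the first fast
#' negative trough within the volley search window; the fEPSP slope is the
#' least-squares line fitted over the 1-ms window starting a fixed offset
#' after the volley trough (the volley endpoint is not sharply defined, so
#' the window is anchored at trough + \code{slopeOffsetMs}).
#'
#' @param sweep a field-potential [TraceSweep-class] in mV with a
#'   \code{stimOnsetS} annotation (optionally \code{stimulusUa},
#'   \code{sweepTimeS}).
#' @param stimOnsetS stimulus time, s; defaults to the annotation.
#' @param blankMs artifact blanking window after the stimulus, ms (default 1).
#' @param volleyWindowMs fiber-volley search window after the stimulus, ms
#'   (default c(1, 4)).
#' @param slopeOffsetMs offset from the volley trough to the start of the
#'   1-ms slope window, ms (default 0.5).
#' @param slopeWindowMs slope-window length, ms (default 1).
#' @param detectSd a sweep is a null measure when no post-stimulus deflection
#'   exceeds this multiple of the baseline robust RMS (default 3); with a
#'   silent baseline (RMS 0) any nonzero deflection counts.
#' @return A [FepspMeasure-class]; \code{detected = FALSE} flags a null
#'   measure.
#' @export
measureFepsp <- function(sweep, stimOnsetS = NULL, blankMs = 1,
                         volleyWindowMs = c(1, 4), slopeOffsetMs = 0.5,
                         slopeWindowMs = 1, detectSd = 3) {
  stopifnot(is(sweep, "TraceSweep"))
  if (is.null(stimOnsetS)) stimOnsetS <- sweep@annotations$stimOnsetS
  if (is.null(stimOnsetS)) stop("stimulus-onset annotation required")
  fs <- sweep@samplingRateHz
  x <- sweep@samples
  iStim <- round(stimOnsetS * fs)
  base <- mean(x[seq_len(max(1L, iStim))])
  rms <- stats::mad(x[seq_len(max(1L, iStim))])
  nullMeasure <- new("FepspMeasure", fiberVolleyMv = NA_real_,
                     slopeMvMs = NA_real_,
                     stimulusUa = sweep@annotations$stimulusUa %||% NA_real_,
                     sweepTimeS = sweep@annotations$sweepTimeS %||% NA_real_,
                     detected = FALSE)
  post <- (iStim + round(blankMs / 1000 * fs)):length(x)
  dev <- abs(x[post] - base)
  if (all(dev <= max(detectSd * rms, .Machine$double.eps^0.5 * max(1, abs(base)))))
    return(nullMeasure)
  vw <- iStim + round(volleyWindowMs / 1000 * fs)
  vIdx <- max(2L, vw[1]):min(length(x) - 1L, vw[2])
  # fiber volley = FIRST fast negative trough in the search window, not the
  # deepest point (the fEPSP itself can dip lower inside the window): local
  # minima at least volleyFraction of the deepest in-window deviation
  d <- x[vIdx] - base
  deepest <- -min(d)
  isMin <- x[vIdx] < x[vIdx - 1L] & x[vIdx] <= x[vIdx + 1L]
  qualifies <- isMin & (-d) >= max(detectSd * rms, 0.1 * deepest)
  trough <- if (any(qualifies)) vIdx[which(qualifies)[1]]
  else vIdx[which.min(x[vIdx])]
  volley <- base - x[trough]
  s0 <- trough + round(slopeOffsetMs / 1000 * fs)
  s1 <- s0 + round(slopeWindowMs / 1000 * fs)
  if (s1 > length(x)) return(nullMeasure)
  idx <- s0:s1
  tMs <- (idx - idx[1]) / fs * 1000
  slope <- stats::cov(tMs, x[idx]) / stats::var(tMs)
  new("FepspMeasure", fiberVolleyMv = volley, slopeMvMs = slope,
      stimulusUa = sweep@annotations$stimulusUa %||% NA_real_,
      sweepTimeS = sweep@annotations$sweepTimeS %||% NA_real_,
      detected = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Input-output curve from fEPSP measurements
#'
#' Sorted (fiber-volley amplitude, slope) pairs with the linear-fit gain
#' (slope per mV of fiber volley) quantifying basal synaptic transmission.
#'
#' @param measures list of [FepspMeasure-class] (null measures are dropped).
#' @return A list with \code{curve} (data.frame \code{fiber_volley_mv,
#'   slope_mv_ms}, sorted by volley), \code{gain}, \code{intercept} and
#'   \code{r_squared}; the fit entries are NA when all volley amplitudes
#'   coincide.
#' @export
inputOutputCurve <- function(measures) {
  stopifnot(all(vapply(measures, is, logical(1), "FepspMeasure")))
  ok <- vapply(measures, function(m) m@detected, logical(1))
  if (sum(ok) < 2L) stop("at least two detected measures required")
  fv <- vapply(measures[ok], function(m) m@fiberVolleyMv, numeric(1))
  sl <- vapply(measures[ok], function(m) m@slopeMvMs, numeric(1))
  ord <- order(fv)
  curve <- data.frame(fiber_volley_mv = fv[ord], slope_mv_ms = sl[ord])
  if (length(unique(fv)) < 2L)
    return(list(curve = curve, gain = NA_real_, intercept = NA_real_,
                r_squared = NA_real_))
  fit <- stats::lm(slope_mv_ms ~ fiber_volley_mv, data = curve)
  list(curve = curve, gain = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Paired-pulse ratios
#'
#' For sweeps carrying two stimuli, the ratio of the second fEPSP slope to
#' the first, per inter-pulse interval; ratios above 1 indicate facilitation.
#'
#' @param sweeps list of [TraceSweep-class], each annotated with
#'   \code{stimOnsetS} (first pulse) and \code{stim2OnsetS} (second pulse).
#' @param ... passed to [measureFepsp()].
#' @return data.frame with columns \code{interval_ms}, \code{slope1_mv_ms},
#'   \code{slope2_mv_ms}, \code{ratio} (NA, flagged by a warning, where the
#'   first slope is zero or a response is undetectable).
#' @export
pairedPulseRatio <- function(sweeps, ...) {
  rows <- lapply(sweeps, function(sw) {
    stopifnot(is(sw, "TraceSweep"))
    t1 <- sw@annotations$stimOnsetS
    t2 <- sw@annotations$stim2OnsetS
    if (is.null(t1) || is.null(t2)) stop("both stimulus annotations required")
    fs <- sw@samplingRateHz
    n1 <- round(t2 * fs) - 1L
    sw1 <- traceSweep(sw@samples[seq_len(n1)], fs, sw@units,
                      sw@baselineWindowS, list(stimOnsetS = t1))
    m1 <- measureFepsp(sw1, ...)
    # second response measured on the tail with a short LOCAL pre-stimulus
    # baseline, so the first response cannot contaminate its baseline
    pre <- max(1L, round((t2 - 0.005) * fs))
    sw2 <- traceSweep(sw@samples[pre:length(sw@samples)], fs, sw@units,
                      c(0, (round(t2 * fs) - pre) / fs),
                      list(stimOnsetS = t2 - (pre - 1L) / fs))
    m2 <- measureFepsp(sw2, ...)
    s1 <- m1@slopeMvMs; s2 <- m2@slopeMvMs
    ratio <- if (!m1@detected || !m2@detected || is.na(s1) || s1 == 0) {
      warning("undefined paired-pulse ratio (first slope zero or undetected)")
      NA_real_
    } else s2 / s1
    data.frame(interval_ms = (t2 - t1) * 1000, slope1_mv_ms = s1,
               slope2_mv_ms = s2, ratio = ratio)
  })
  do.call(rbind, rows)
}

#' Theta-burst pulse timestamps
#'
#' Expands an induction protocol into the sorted timestamps of every pulse:
#' trains at \code{interTrainIntervalS} spacing, bursts at the burst rate
#' within each train, pulses at the intra-burst frequency within each burst.
#'
#' @param protocol an [InductionProtocol-class].
#' @return Strictly increasing numeric vector of pulse times, s. The default
#'   protocol yields 200 pulses, the last at 41.83 s.
#' @examples
#' pt <- thetaBurstTimes(inductionProtocol())
#' length(pt); utils::tail(pt, 1)
#' @export
thetaBurstTimes <- function(protocol) {
  stopifnot(is(protocol, "InductionProtocol"))
  nBurst <- floor(protocol@trainDurationS * protocol@burstRateHz)
  trainStarts <- (seq_len(protocol@trainCount) - 1L) *
    protocol@interTrainIntervalS
  burstStarts <- (seq_len(nBurst) - 1L) / protocol@burstRateHz
  pulseOffsets <- (seq_len(protocol@pulsesPerBurst) - 1L) / protocol@burstHz
  t <- as.vector(outer(pulseOffsets,
                       as.vector(outer(burstStarts, trainStarts, "+")), "+"))
  sort(t)
}

#' Normalize an LTP time course to its baseline
#'
#' Each slope is expressed as a percentage of the mean slope over the
#' baseline window (the \code{baselineWindowMin} minutes preceding
#' induction). Normalizing an already-normalized course is the identity.
#'
#' @param tc an [LTPTimecourse-class].
#' @return data.frame with columns \code{time_s}, \code{time_min} (relative
#'   to induction) and \code{normalized_pct}.
#' @export
normalizeTimecourse <- function(tc) {
  stopifnot(is(tc, "LTPTimecourse"))
  pre <- tc@timesS <= tc@inductionTimeS &
    tc@timesS > tc@inductionTimeS - tc@baselineWindowMin * 60
  if (!any(pre)) stop("no baseline sweeps in the baseline window")
  b <- mean(tc@slopesMvMs[pre])
  if (!(abs(b) > 0)) stop("invalid baseline: mean baseline slope is zero")
  data.frame(time_s = tc@timesS,
             time_min = (tc@timesS - tc@inductionTimeS) / 60,
             normalized_pct = 100 * tc@slopesMvMs / b)
}

#' LTP magnitude over the final window
#'
#' Mean baseline-normalized fEPSP slope (percent of baseline) over the final
#' \code{magnitudeWindowMin} minutes of the recording; 100% means no
#' potentiation.
#'
#' @param tc an [LTPTimecourse-class] with at least
#'   \code{magnitudeWindowMin} minutes of post-induction data.
#' @return LTP magnitude, percent.
#' @examples
#' tc <- genLTPSession(-0.2, 1.65, noiseCv = 0)
#' ltpMagnitude(tc)  # 165
#' @export
ltpMagnitude <- function(tc) {
  stopifnot(is(tc, "LTPTimecourse"))
  norm <- normalizeTimecourse(tc)
  tEnd <- max(tc@timesS)
  if (tEnd - tc@inductionTimeS < tc@magnitudeWindowMin * 60)
    stop("insufficient post-induction data for the magnitude window")
  last <- tc@timesS > tEnd - tc@magnitudeWindowMin * 60
  mean(norm$normalized_pct[last])
}
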