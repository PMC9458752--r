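#' @import methods
NULL

#' Visual stimulation protocol
#'
#' Describes the drifting-grating protocol used for single-unit ocular
#' dominance recordings: gratings at equally spaced orientations shown to each
#' eye in turn, with interleaved blank trials for baseline firing.
#'
#' @slot nOrientations integer, number of equally spaced grating orientations.
#' @slot stimDurationS seconds of grating presentation within a trial.
#' @slot trialDurationS total trial length in seconds.
#' @slot repeatsPerCondition repeats of each eye x orientation condition.
#' @slot spatialFrequencyCpd grating spatial frequency, cycles/degree.
#' @slot contrast grating contrast, fraction in (0, 1].
#' @slot eyes ordered eye labels, by convention \code{c("contra", "ipsi")}.
#' @slot includesBlank logical, whether blank trials are part of the design.
#'
#' @seealso [stimProtocol()] for the user-facing constructor with defaults.
#' @export
setClass("StimProtocol", representation(
  nOrientations = "integer",
  stimDurationS = "numeric",
  trialDurationS = "numeric",
  repeatsPerCondition = "integer",
  spatialFrequencyCpd = "numeric",
  contrast = "numeric",
  eyes = "character",
  includesBlank = "logical"
))

setValidity("StimProtocol", function(object) {
  msg <- character()
  if (object@nOrientations < 1L) msg <- c(msg, "nOrientations must be >= 1")
  if (object@repeatsPerCondition < 1L) msg <- c(msg, "repeatsPerCondition must be >= 1")
  if (!(object@stimDurationS > 0)) msg <- c(msg, "stimDurationS must be > 0")
  if (!(object@stimDurationS < object@trialDurationS))
    msg <- c(msg, "stimDurationS must be < trialDurationS")
  if (length(object@eyes) != 2L) msg <- c(msg, "exactly two eye labels required")
  if (length(msg)) msg else TRUE
})

#' Construct a stimulation protocol
#'
#' Defaults describe the standard critical-period assay: 0.1 cycle/degree,
#' 95% contrast sinusoidal gratings at twelve equally spaced orientations,
#' each shown for 2 s within a 4-s trial, three repeats per eye and
#' orientation, with blank trials for baseline firing.
#'
#' @param nOrientations number of orientations (default 12).
#' @param stimDurationS stimulus-on time per trial, s (default 2).
#' @param trialDurationS trial length, s (default 4).
#' @param repeatsPerCondition repeats per eye x orientation (default 3).
#' @param spatialFrequencyCpd spatial frequency, cycles/degree (default 0.1).
#' @param contrast contrast fraction (default 0.95).
#' @param eyes eye labels in order (default \code{c("contra", "ipsi")}).
#' @param includesBlank include blank trials (default TRUE).
#' @return A [StimProtocol-class] object.
#' @examples
#' stimProtocol()
#' @export
stimProtocol <- function(nOrientations = 12L, stimDurationS = 2,
                         trialDurationS = 4, repeatsPerCondition = 3L,
                         spatialFrequencyCpd = 0.1, contrast = 0.95,
                         eyes = c("contra", "ipsi"), includesBlank = TRUE) {
  new("StimProtocol",
      nOrientations = as.integer(nOrientations),
      stimDurationS = stimDurationS, trialDurationS = trialDurationS,
      repeatsPerCondition = as.integer(repeatsPerCondition),
      spatialFrequencyCpd = spatialFrequencyCpd, contrast = contrast,
      eyes = eyes, includesBlank = includesBlank)
}

#' Orientations of a protocol
#' @param protocol A [StimProtocol-class].
#' @return Numeric vector of orientations in degrees, equally spaced over
#'   \[0, 360).
#' @export
protocolOrientations <- function(protocol) {
  n <- protocol@nOrientations
  seq(0, 360 - 360 / n, by = 360 / n)
}

#' Ground truth for the ocular-dominance generator
#'
#' Population parameters from which per-unit firing is simulated, plus the
#' monocular-deprivation (MD) effect the downstream pipeline must detect.
#' MD is modelled as a multiplicative reduction of the deprived
#' (contralateral) eye's drive: effective contra drive =
#' \code{contraDriveHz * (1 - mdShift)}.
#'
#' @slot contraDriveHz mean evoked drive through the contralateral eye, Hz.
#' @slot ipsiDriveHz mean evoked drive through the ipsilateral eye, Hz.
#' @slot baselineRateHz spontaneous rate, Hz.
#' @slot tuningKappa von Mises concentration of the orientation tuning.
#' @slot mdShift fraction in \[0, 1\]; multiplicative reduction of the
#'   deprived-eye drive (0 = no deprivation effect).
#' @slot driveSdLog lognormal sd of across-unit drive variability.
#' @slot units data.frame of realized per-unit parameters, filled in by
#'   [genODDataset()] (empty before generation).
#' @export
setClass("ODGroundTruth", representation(
  contraDriveHz = "numeric",
  ipsiDriveHz = "numeric",
  baselineRateHz = "numeric",
  tuningKappa = "numeric",
  mdShift = "numeric",
  driveSdLog = "numeric",
  units = "data.frame"
))

setValidity("ODGroundTruth", function(object) {
  msg <- character()
  if (object@contraDriveHz < 0 || object@ipsiDriveHz < 0 ||
      object@baselineRateHz < 0) msg <- c(msg, "drives and baseline must be >= 0")
  if (object@mdShift < 0 || object@mdShift > 1) msg <- c(msg, "mdShift must be in [0, 1]")
  if (object@driveSdLog < 0) msg <- c(msg, "driveSdLog must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct OD ground truth
#'
#' Defaults emulate a contralaterally dominated binocular-zone population:
#' baseline 2 Hz, contra drive 10 Hz, ipsi drive 5 Hz with lognormal
#' across-unit spread, so the expected non-deprived contralateral bias index
#' is about 0.67.
#'
#' @param contraDriveHz mean contra-eye drive, Hz (default 10).
#' @param ipsiDriveHz mean ipsi-eye drive, Hz (default 5).
#' @param baselineRateHz spontaneous rate, Hz (default 2).
#' @param tuningKappa orientation-tuning concentration (default 4, about a
#'   30-degree half-width at half height, typical of mouse V1 tuning).
#' @param mdShift multiplicative deprived-eye drive reduction in \[0,1\]
#'   (default 0 = no deprivation).
#' @param driveSdLog lognormal sd of per-unit drive variability (default 0.35).
#' @return An [ODGroundTruth-class] object.
#' @export
odGroundTruth <- function(contraDriveHz = 10, ipsiDriveHz = 5,
                          baselineRateHz = 2, tuningKappa = 4,
                          mdShift = 0, driveSdLog = 0.35) {
  new("ODGroundTruth", contraDriveHz = contraDriveHz, ipsiDriveHz = ipsiDriveHz,
      baselineRateHz = baselineRateHz, tuningKappa = tuningKappa,
      mdShift = mdShift, driveSdLog = driveSdLog,
      units = data.frame())
}

#' Adaptive integrate-and-fire parameters
#'
#' Parameters of the leaky integrate-and-fire neuron with spike-triggered
#' adaptation used to emulate current-clamp step responses.
#'
#' @slot resistanceMohm membrane resistance, megaohm.
#' @slot capacitancePf membrane capacitance, pF.
#' @slot restMv resting potential, mV.
#' @slot thresholdMv spike threshold, mV.
#' @slot resetMv post-spike reset potential, mV.
#' @slot refractoryMs absolute refractory period, ms.
#' @slot adaptIncrementPa spike-triggered adaptation-current increment, pA.
#' @slot adaptTauMs adaptation-current decay time constant, ms.
#' @slot noiseSdMv membrane-noise standard deviation, mV.
#' @export
setClass("IFParams", representation(
  resistanceMohm = "numeric", capacitancePf = "numeric",
  restMv = "numeric", thresholdMv = "numeric", resetMv = "numeric",
  refractoryMs = "numeric", adaptIncrementPa = "numeric",
  adaptTauMs = "numeric", noiseSdMv = "numeric"
))

setValidity("IFParams", function(object) {
  msg <- character()
  if (!(object@resistanceMohm > 0)) msg <- c(msg, "resistance must be > 0")
  if (!(object@capacitancePf > 0)) msg <- c(msg, "capacitance must be > 0")
  if (!(object@adaptTauMs > 0)) msg <- c(msg, "adaptTauMs must be > 0")
  if (!(object@thresholdMv > object@resetMv)) msg <- c(msg, "threshold must exceed reset")
  if (object@noiseSdMv < 0) msg <- c(msg, "noiseSdMv must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct integrate-and-fire parameters
#'
#' Defaults approximate a layer-5 pyramidal neuron: 200 MOhm, 100 pF
#' (membrane time constant 20 ms), rest -70 mV, threshold -40 mV.
#'
#' @param resistanceMohm membrane resistance, MOhm (default 200).
#' @param capacitancePf membrane capacitance, pF (default 100).
#' @param restMv resting potential, mV (default -70).
#' @param thresholdMv spike threshold, mV (default -40).
#' @param resetMv reset potential, mV (default -60).
#' @param refractoryMs refractory period, ms (default 2).
#' @param adaptIncrementPa adaptation increment per spike, pA (default 0).
#' @param adaptTauMs adaptation decay time constant, ms (default 100).
#' @param noiseSdMv membrane noise sd, mV (default 0).
#' @return An [IFParams-class] object.
#' @export
ifParams <- function(resistanceMohm = 200, capacitancePf = 100,
                     restMv = -70, thresholdMv = -40, resetMv = -60,
                     refractoryMs = 2, adaptIncrementPa = 0,
                     adaptTauMs = 100, noiseSdMv = 0) {
  new("IFParams", resistanceMohm = resistanceMohm, capacitancePf = capacitancePf,
      restMv = restMv, thresholdMv = thresholdMv, resetMv = resetMv,
      refractoryMs = refractoryMs, adaptIncrementPa = adaptIncrementPa,
      adaptTauMs = adaptTauMs, noiseSdMv = noiseSdMv)
}

#' Ground truth for miniature-PSC simulation
#'
#' Event times and amplitudes, biexponential kinetics, noise level and
#' polarity from which a synthetic miniature postsynaptic-current sweep is
#' rendered. Amplitudes are positive magnitudes; polarity determines the
#' rendered sign (inward events deflect negative).
#'
#' @slot eventTimesS strictly increasing event times, s.
#' @slot amplitudesPa positive event peak amplitudes, pA.
#' @slot riseTauMs rise time constant, ms.
#' @slot decayTauMs decay time constant, ms (must exceed rise).
#' @slot noiseSdPa Gaussian noise sd, pA.
#' @slot polarity "inward" or "outward".
#' @export
setClass("MiniGroundTruth", representation(
  eventTimesS = "numeric", amplitudesPa = "numeric",
  riseTauMs = "numeric", decayTauMs = "numeric",
  noiseSdPa = "numeric", polarity = "character"
))

setValidity("MiniGroundTruth", function(object) {
  msg <- character()
  if (length(object@eventTimesS) != length(object@amplitudesPa))
    msg <- c(msg, "times and amplitudes must have equal length")
  if (any(object@amplitudesPa <= 0)) msg <- c(msg, "amplitudes must be > 0")
  if (is.unsorted(object@eventTimesS, strictly = TRUE))
    msg <- c(msg, "event times must be strictly increasing")
  if (!(object@decayTauMs > object@riseTauMs))
    msg <- c(msg, "decayTauMs must exceed riseTauMs")
  if (!object@polarity %in% c("inward", "outward"))
    msg <- c(msg, "polarity must be 'inward' or 'outward'")
  if (length(msg)) msg else TRUE
})

#' Construct mini-event ground truth
#'
#' @param eventTimesS strictly increasing event times, s.
#' @param amplitudesPa positive peak amplitudes, pA (recycled to the number of
#'   events).
#' @param riseTauMs rise time constant, ms (default 0.5).
#' @param decayTauMs decay time constant, ms (default 5).
#' @param noiseSdPa noise sd, pA (default 0).
#' @param polarity "inward" (default) or "outward".
#' @return A [MiniGroundTruth-class] object.
#' @export
miniGroundTruth <- function(eventTimesS, amplitudesPa, riseTauMs = 0.5,
                            decayTauMs = 5, noiseSdPa = 0,
                            polarity = "inward") {
  amplitudesPa <- rep_len(amplitudesPa, length(eventTimesS))
  new("MiniGroundTruth", eventTimesS = as.numeric(eventTimesS),
      amplitudesPa = as.numeric(amplitudesPa), riseTauMs = riseTauMs,
      decayTauMs = decayTauMs, noiseSdPa = noiseSdPa, polarity = polarity)
}

#' A uniformly sampled recording sweep
#'
#' One current- or voltage-clamp sweep with sampling rate, units and
#' stimulus annotations (step amplitude/onset/offset, laser onset, etc.).
#'
#' @slot samples numeric sample vector (pA for voltage clamp, mV for current
#'   clamp).
#' @slot samplingRateHz sampling rate, Hz.
#' @slot units units label for the samples ("pA" or "mV").
#' @slot baselineWindowS two-element window (start, end) in seconds used for
#'   baseline estimation.
#' @slot annotations named list of stimulus annotations; recognised names
#'   include \code{stepPa}, \code{stepMv}, \code{stepOnsetS}, \code{stepOffsetS},
#'   \code{laserOnsetS}, \code{stimOnsetS}.
#' @export
setClass("TraceSweep", representation(
  samples = "numeric", samplingRateHz = "numeric", units = "character",
  baselineWindowS = "numeric", annotations = "list"
))

setValidity("TraceSweep", function(object) {
  msg <- character()
  if (!(object@samplingRateHz > 0)) msg <- c(msg, "samplingRateHz must be > 0")
  if (length(object@baselineWindowS) != 2L ||
      object@baselineWindowS[1] > object@baselineWindowS[2])
    msg <- c(msg, "baselineWindowS must be an ordered (start, end) pair")
  dur <- length(object@samples) / object@samplingRateHz
  ann <- object@annotations
  for (nm in intersect(names(ann), c("stepOnsetS", "stepOffsetS", "laserOnsetS",
                                     "stimOnsetS"))) {
    v <- ann[[nm]]
    if (is.numeric(v) && length(v) && any(v < 0 | v > dur))
      msg <- c(msg, sprintf("annotation '%s' outside sweep", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a trace sweep
#'
#' @param samples numeric samples.
#' @param samplingRateHz sampling rate, Hz.
#' @param units units label, "pA" or "mV".
#' @param baselineWindowS baseline (start, end) in s; defaults to the first
#'   10% of the sweep.
#' @param annotations named list of stimulus annotations.
#' @return A [TraceSweep-class] object.
#' @export
traceSweep <- function(samples, samplingRateHz, units = "pA",
                       baselineWindowS = NULL, annotations = list()) {
  if (is.null(baselineWindowS)) {
    baselineWindowS <- c(0, 0.1 * length(samples) / samplingRateHz)
  }
  new("TraceSweep", samples = as.numeric(samples),
      samplingRateHz = samplingRateHz, units = units,
      baselineWindowS = baselineWindowS, annotations = annotations)
}

#' Sweep duration in seconds
#' @param sweep A [TraceSweep-class].
#' @return Duration, s.
#' @export
sweepDuration <- function(sweep) length(sweep@samples) / sweep@samplingRateHz

#' Sample times of a sweep
#' @param sweep A [TraceSweep-class].
#' @return Numeric vector of sample times (s), starting at 0.
#' @export
sweepTimes <- function(sweep) {
  (seq_along(sweep@samples) - 1L) / sweep@samplingRateHz
}

#' Current-clamp step session
#'
#' One voltage sweep per injected current step, with the generating
#' integrate-and-fire parameters and ground-truth spike times when produced
#' by [genCurrentStepSession()].
#'
#' @slot sweeps list of [TraceSweep-class], one per step, in step order.
#' @slot stepsPa injected step amplitudes, pA.
#' @slot stepOnsetS step onset within each sweep, s.
#' @slot stepDurationS step duration, s.
#' @slot params the [IFParams-class] used (for synthetic sessions).
#' @slot truthSpikeTimes list of numeric vectors of ground-truth spike
#'   times (s), parallel to \code{sweeps}.
#' @export
setClass("CurrentClampSession", representation(
  sweeps = "list", stepsPa = "numeric", stepOnsetS = "numeric",
  stepDurationS = "numeric", params = "IFParams", truthSpikeTimes = "list"
))

setValidity("CurrentClampSession", function(object) {
  if (length(object@sweeps) != length(object@stepsPa))
    "one sweep per current step required" else TRUE
})

#' LSPS stimulation-grid geometry
#'
#' Uncaging-site grid for laser-scanning photostimulation mapping. The top
#' row (row 1) is aligned with the pia; site depth below pia is
#' \code{(row - 1) * spacingUm}.
#'
#' @slot rows number of grid rows (default 16).
#' @slot cols number of grid columns (default 16).
#' @slot spacingUm site spacing, micrometres (default 75).
#' @slot somaRow soma row coordinate (possibly fractional).
#' @slot somaCol soma column coordinate (possibly fractional).
#' @export
setClass("LSPSGrid", representation(
  rows = "integer", cols = "integer", spacingUm = "numeric",
  somaRow = "numeric", somaCol = "numeric"
))

setValidity("LSPSGrid", function(object) {
  msg <- character()
  if (!(object@spacingUm > 0)) msg <- c(msg, "spacingUm must be > 0")
  if (object@somaRow < 1 || object@somaRow > object@rows ||
      object@somaCol < 1 || object@somaCol > object@cols)
    msg <- c(msg, "soma must lie inside the grid")
  if (length(msg)) msg else TRUE
})

#' Construct an LSPS grid
#'
#' @param rows,cols grid dimensions (default 16 x 16).
#' @param spacingUm site spacing, um (default 75).
#' @param somaRow,somaCol soma coordinates in grid units (default row 8,
#'   column 8.5: a layer-5 soma near the grid's horizontal centre).
#' @return An [LSPSGrid-class] object.
#' @export
lspsGrid <- function(rows = 16L, cols = 16L, spacingUm = 75,
                     somaRow = 8, somaCol = 8.5) {
  new("LSPSGrid", rows = as.integer(rows), cols = as.integer(cols),
      spacingUm = spacingUm, somaRow = somaRow, somaCol = somaCol)
}

#' Site depths below pia
#' @param grid An [LSPSGrid-class].
#' @return Numeric vector of per-row depths (um), top row at 0.
#' @export
gridRowDepthsUm <- function(grid) (seq_len(grid@rows) - 1L) * grid@spacingUm

#' LSPS mapping recording for one cell
#'
#' One voltage-clamp sweep per stimulation site (site-major, rows within
#' columns as produced by [genLSPSDataset()]), with grid geometry and holding
#' potential. Holding -70 mV isolates excitatory (inward) currents; 0 mV
#' isolates inhibitory (outward) currents.
#'
#' @slot grid the [LSPSGrid-class].
#' @slot holdingMv holding potential, mV.
#' @slot sweeps list of [TraceSweep-class], one per site, ordered row-major
#'   (site index = (row - 1) * cols + col).
#' @slot cellId cell identifier.
#' @slot group group label (e.g. genotype).
#' @export
setClass("LSPSRecording", representation(
  grid = "LSPSGrid", holdingMv = "numeric", sweeps = "list",
  cellId = "character", group = "character"
))

setValidity("LSPSRecording", function(object) {
  n <- object@grid@rows * object@grid@cols
  msg <- character()
  if (length(object@sweeps) != n)
    msg <- c(msg, sprintf("expected %d sweeps (one per site), got %d",
                          n, length(object@sweeps)))
  rates <- vapply(object@sweeps, function(s) s@samplingRateHz, numeric(1))
  if (length(rates) && length(unique(rates)) != 1L)
    msg <- c(msg, "all sweeps must share one sampling rate")
  if (length(msg)) msg else TRUE
})

#' Synaptic input map
#'
#' Per-site response class and amplitude for one mapped cell. Sign
#' convention: excitatory (inward) synaptic amplitudes are <= 0, inhibitory
#' (outward) >= 0; class "none" sites carry amplitude 0; "direct" and
#' "excluded" sites are dropped from synaptic statistics.
#'
#' @slot grid the [LSPSGrid-class].
#' @slot mode "excitatory" or "inhibitory".
#' @slot classes character matrix (rows x cols) with values in
#'   \{"direct", "synaptic", "none", "excluded"\}.
#' @slot amplitudesPa numeric matrix of signed site amplitudes, pA.
#' @export
setClass("InputMap", representation(
  grid = "LSPSGrid", mode = "character", classes = "matrix",
  amplitudesPa = "matrix"
))

setValidity("InputMap", function(object) {
  msg <- character()
  dm <- c(object@grid@rows, object@grid@cols)
  if (!identical(dim(object@classes), as.integer(dm)) ||
      !identical(dim(object@amplitudesPa), as.integer(dm)))
    msg <- c(msg, "class/amplitude matrices must match grid dimensions")
  if (!object@mode %in% c("excitatory", "inhibitory"))
    msg <- c(msg, "mode must be 'excitatory' or 'inhibitory'")
  bad <- setdiff(unique(as.vector(object@classes)),
                 c("direct", "synaptic", "none", "excluded"))
  if (length(bad)) msg <- c(msg, paste("unknown site class:", bad[1]))
  none <- object@classes == "none"
  if (any(object@amplitudesPa[none] != 0))
    msg <- c(msg, "'none' sites must carry amplitude 0")
  syn <- object@classes == "synaptic"
  if (object@mode == "excitatory" && any(object@amplitudesPa[syn] > 0))
    msg <- c(msg, "excitatory synaptic amplitudes must be <= 0")
  if (object@mode == "inhibitory" && any(object@amplitudesPa[syn] < 0))
    msg <- c(msg, "inhibitory synaptic amplitudes must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Site classes of an input map
#' @param map An [InputMap-class].
#' @return Character matrix of site classes.
#' @export
siteClasses <- function(map) map@classes

#' Site amplitudes of an input map
#' @param map An [InputMap-class].
#' @return Numeric matrix of signed amplitudes (pA).
#' @export
siteAmplitudes <- function(map) map@amplitudesPa

#' LTP slope time course
#'
#' Field-EPSP slope measurements sampled at a fixed inter-sweep interval
#' around an induction event. Slopes are stored raw (mV/ms); normalization to
#' the baseline mean is performed by [normalizeTimecourse()] /
#' [ltpMagnitude()].
#'
#' @slot timesS sweep times, s (induction at \code{inductionTimeS}).
#' @slot slopesMvMs raw fEPSP slopes, mV/ms.
#' @slot inductionTimeS time of the induction protocol, s.
#' @slot baselineWindowMin length of the pre-induction baseline window used
#'   for normalization, minutes.
#' @slot magnitudeWindowMin length of the final window scored as the LTP
#'   magnitude, minutes.
#' @export
setClass("LTPTimecourse", representation(
  timesS = "numeric", slopesMvMs = "numeric", inductionTimeS = "numeric",
  baselineWindowMin = "numeric", magnitudeWindowMin = "numeric"
))

setValidity("LTPTimecourse", function(object) {
  msg <- character()
  if (length(object@timesS) != length(object@slopesMvMs))
    msg <- c(msg, "times and slopes must have equal length")
  if (is.unsorted(object@timesS)) msg <- c(msg, "times must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Construct an LTP time course
#'
#' @param timesS sweep times, s.
#' @param slopesMvMs raw slopes, mV/ms.
#' @param inductionTimeS induction time, s.
#' @param baselineWindowMin baseline window, min (default 10).
#' @param magnitudeWindowMin final scoring window, min (default 10).
#' @return An [LTPTimecourse-class] object.
#' @export
ltpTimecourse <- function(timesS, slopesMvMs, inductionTimeS,
                          baselineWindowMin = 10, magnitudeWindowMin = 10) {
  new("LTPTimecourse", timesS = as.numeric(timesS),
      slopesMvMs = as.numeric(slopesMvMs), inductionTimeS = inductionTimeS,
      baselineWindowMin = baselineWindowMin,
      magnitudeWindowMin = magnitudeWindowMin)
}

#' Group summary (mean, SEM, n)
#'
#' Summary-statistics form of a group, as reported in figures
#' (mean +/- s.e.m., n). Used by [tTestGroups()] to recompute two-sample t
#' statistics from printed summaries.
#'
#' @slot mean group mean.
#' @slot sem standard error of the mean.
#' @slot n group size.
#' @export
setClass("GroupSummary", representation(
  mean = "numeric", sem = "numeric", n = "integer"
))

setValidity("GroupSummary", function(object) {
  msg <- character()
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (!(object@sem > 0)) msg <- c(msg, "sem must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a group summary
#' @param mean group mean.
#' @param sem standard error of the mean.
#' @param n group size (>= 2).
#' @return A [GroupSummary-class] object.
#' @examples
#' groupSummary(165.4, 1.24, 8)
#' @export
groupSummary <- function(mean, sem, n) {
  new("GroupSummary", mean = mean, sem = sem, n = as.integer(n))
}

#' Hypothesis-test result
#'
#' @slot statistic test statistic.
#' @slot df degrees of freedom (possibly fractional; NA where undefined).
#' @slot p two-sided p value.
#' @slot method method label.
#' @export
setClass("TestResult", representation(
  statistic = "numeric", df = "numeric", p = "numeric", method = "character"
))

setValidity("TestResult", function(object) {
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    "p must be in [0, 1]" else TRUE
})

testResult <- function(statistic, df, p, method) {
  new("TestResult", statistic = as.numeric(statistic), df = as.numeric(df),
      p = as.numeric(p), method = method)
}
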