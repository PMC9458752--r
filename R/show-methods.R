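setMethod("show", "StimProtocol", function(object) {
  cat(sprintf("StimProtocol: %d orientations, %g cpd, %.0f%% contrast\n",
              object@nOrientations, object@spatialFrequencyCpd,
              100 * object@contrast))
  cat(sprintf("  %g s stimulus in %g s trials, %d repeats/condition, eyes: %s%s\n",
              object@stimDurationS, object@trialDurationS,
              object@repeatsPerCondition, paste(object@eyes, collapse = "/"),
              if (object@includesBlank) ", with blanks" else ""))
})

setMethod("show", "ODGroundTruth", function(object) {
  cat(sprintf(paste0("ODGroundTruth: baseline %g Hz, contra %g Hz, ipsi %g Hz ",
                     "(kappa %g, sdlog %g)\n"),
              object@baselineRateHz, object@contraDriveHz, object@ipsiDriveHz,
              object@tuningKappa, object@driveSdLog))
  cat(sprintf("  mdShift = %g (deprived contra drive x %g); %d realized units\n",
              object@mdShift, 1 - object@mdShift, nrow(object@units)))
})

setMethod("show", "IFParams", function(object) {
  cat(sprintf("IFParams: R = %g MOhm, C = %g pF (tau_m = %g ms)\n",
              object@resistanceMohm, object@capacitancePf,
              object@resistanceMohm * object@capacitancePf / 1000))
  cat(sprintf("  rest %g mV, threshold %g mV, reset %g mV, refractory %g ms\n",
              object@restMv, object@thresholdMv, object@resetMv,
              object@refractoryMs))
  cat(sprintf("  adaptation: %g pA / spike, tau %g ms; noise sd %g mV\n",
              object@adaptIncrementPa, object@adaptTauMs, object@noiseSdMv))
})

setMethod("show", "MiniGroundTruth", function(object) {
  cat(sprintf("MiniGroundTruth: %d %s events, tau_rise %g ms, tau_decay %g ms, noise %g pA\n",
              length(object@eventTimesS), object@polarity,
              object@riseTauMs, object@decayTauMs, object@noiseSdPa))
})

setMethod("show", "TraceSweep", function(object) {
  cat(sprintf("TraceSweep: %d samples @ %g kHz (%.3f s), units %s\n",
              length(object@samples), object@samplingRateHz / 1000,
              sweepDuration(object), object@units))
  if (length(object@annotations))
    cat("  annotations:", paste(names(object@annotations), collapse = ", "), "\n")
})

setMethod("show", "CurrentClampSession", function(object) {
  cat(sprintf("CurrentClampSession: %d steps (%g to %g pA), %g s each\n",
              length(object@stepsPa), min(object@stepsPa), max(object@stepsPa),
              object@stepDurationS))
})

setMethod("show", "LSPSGrid", function(object) {
  cat(sprintf("LSPSGrid: %d x %d sites, %g um spacing, soma at (%g, %g)\n",
              object@rows, object@cols, object@spacingUm,
              object@somaRow, object@somaCol))
})

setMethod("show", "LSPSRecording", function(object) {
  cat(sprintf("LSPSRecording '%s' (%s): %d sites, holding %g mV\n",
              object@cellId, object@group, length(object@sweeps),
              object@holdingMv))
})

setMethod("show", "InputMap", function(object) {
  tab <- table(factor(object@classes,
                      levels = c("direct", "synaptic", "none", "excluded")))
  cat(sprintf("InputMap (%s): %d x %d sites\n", object@mode,
              object@grid@rows, object@grid@cols))
  cat(sprintf("  direct %d, synaptic %d, none %d, excluded %d\n",
              tab["direct"], tab["synaptic"], tab["none"], tab["excluded"]))
})

setMethod("show", "LTPTimecourse", function(object) {
  cat(sprintf("LTPTimecourse: %d sweeps over %.1f min, induction at %.1f min\n",
              length(object@timesS), diff(range(object@timesS)) / 60,
              object@inductionTimeS / 60))
})

setMethod("show", "GroupSummary", function(object) {
  cat(sprintf("GroupSummary: %g +/- %g (n = %d)\n",
              object@mean, object@sem, object@n))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g\n",
              object@method, object@statistic, object@df, object@p))
})
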