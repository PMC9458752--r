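# Single-unit ocular-dominance pipeline: orientation tuning, the 50%
# inclusion rule, ODI, the seven-category scheme, per-mouse CBI, and the
# ND-vs-MD group comparison.

#' Orientation tuning of one unit
#'
#' Per-eye, per-orientation firing rates for a single unit, raw and
#' baseline-subtracted, with the preferred orientation per eye.
#'
#' @slot unitId unit identifier.
#' @slot orientationsDeg orientation values, degrees.
#' @slot rawRateHz eyes x orientations matrix of mean stimulus-window rates.
#' @slot blankRateHz mean blank-trial rate, Hz.
#' @slot evokedRateHz eyes x orientations matrix of baseline-subtracted
#'   rates (raw minus blank).
#' @slot preferredDeg named per-eye preferred orientation (argmax of the
#'   evoked rate; ties broken toward the lowest orientation).
#' @slot preferredEvokedHz named per-eye evoked rate at that eye's preferred
#'   orientation.
#' @export
setClass("OrientationTuning", representation(
  unitId = "character", orientationsDeg = "numeric", rawRateHz = "matrix",
  blankRateHz = "numeric", evokedRateHz = "matrix", preferredDeg = "numeric",
  preferredEvokedHz = "numeric"
))

setValidity("OrientationTuning", function(object) {
  msg <- character()
  if (object@blankRateHz < 0) msg <- c(msg, "blank rate must be >= 0")
  if (ncol(object@rawRateHz) != length(object@orientationsDeg))
    msg <- c(msg, "rate matrix must have one column per orientation")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OrientationTuning", function(object) {
  cat(sprintf("OrientationTuning '%s': blank %.2f Hz\n",
              object@unitId, object@blankRateHz))
  for (e in rownames(object@rawRateHz))
    cat(sprintf("  %s: preferred %g deg, evoked %.2f Hz\n", e,
                object@preferredDeg[e], object@preferredEvokedHz[e]))
})

#' Per-unit ocular-dominance result
#'
#' @slot unitId unit identifier.
#' @slot ceHz contralateral-eye response, Hz (rectified at 0).
#' @slot ieHz ipsilateral-eye response, Hz (rectified at 0).
#' @slot odi ocular dominance index (IE - CE)/(IE + CE); NA when both
#'   responses are 0.
#' @slot category seven-category assignment, integer 1..7 (NA when odi is NA).
#' @slot included logical, passed the 50% inclusion rule (and has a defined
#'   ODI).
#' @export
setClass("ODUnitResult", representation(
  unitId = "character", ceHz = "numeric", ieHz = "numeric", odi = "numeric",
  category = "integer", included = "logical"
))

setMethod("show", "ODUnitResult", function(object) {
  cat(sprintf("ODUnitResult '%s': CE %.2f Hz, IE %.2f Hz, ODI %.3f, category %s, %s\n",
              object@unitId, object@ceHz, object@ieHz, object@odi,
              ifelse(is.na(object@category), "NA", object@category),
              if (object@included) "included" else "excluded"))
})

#' Group comparison of ocular dominance
#'
#' @slot unitResults data.frame of per-unit results across both conditions
#'   (columns \code{condition, mouse_id, unit_id, blank_hz, raw_pref_hz,
#'   ce_hz, ie_hz, odi, category, included}).
#' @slot mouseSummaries data.frame of per-mouse category counts and CBI
#'   (columns \code{condition, mouse_id, n1..n7, N, cbi}).
#' @slot ksTest [TestResult-class]: two-sample K-S on pooled per-unit ODI.
#' @slot cbiTest [TestResult-class]: two-sample t on per-mouse CBI.
#' @slot categoryHistogram 2 x 7 matrix of category counts per condition.
#' @slot droppedMice character, mice with no included units.
#' @export
setClass("ODGroupResult", representation(
  unitResults = "data.frame", mouseSummaries = "data.frame",
  ksTest = "TestResult", cbiTest = "TestResult",
  categoryHistogram = "matrix", droppedMice = "character"
))

setMethod("show", "ODGroupResult", function(object) {
  ms <- object@mouseSummaries
  for (cond in unique(ms$condition)) {
    v <- ms$cbi[ms$condition == cond]
    cat(sprintf("  %s: %d mice, mean CBI %.3f +/- %.3f\n", cond, length(v),
                mean(v), stats::sd(v) / sqrt(length(v))))
  }
  cat(sprintf("  ODI K-S: D = %.3f, p = %.3g; CBI t(%g) = %.3g, p = %.3g\n",
              object@ksTest@statistic, object@ksTest@p,
              object@cbiTest@df, object@cbiTest@statistic, object@cbiTest@p))
})

# Vectorized per-unit statistics for a whole trial table. Returns one row
# per unit. responseAt = "global": CE/IE taken at the unit's best orientation
# over both eyes; "pereye": at each eye's own preferred orientation.
.odUnitTable <- function(trials, protocol, responseAt = c("global", "pereye")) {
  responseAt <- match.arg(responseAt)
  .checkTrialTable(trials)
  eyes <- protocol@eyes
  orients <- protocolOrientations(protocol)
  stim <- trials[trials$eye != "blank", , drop = FALSE]
  blank <- trials[trials$eye == "blank", , drop = FALSE]
  if (!nrow(blank)) stop("missing blank trials: baseline rate undefined")
  badEye <- setdiff(unique(stim$eye), eyes)
  if (length(badEye)) stop("unknown eye label: ", paste(badEye, collapse = ", "))
  if (!all(unique(stim$orientation_deg) %in% orients))
    stop("trial orientations do not match the protocol")
  units <- sort(unique(trials$unit_id))
  uf <- factor(stim$unit_id, levels = units)
  rate <- stim$spike_count / stim$stim_s
  R <- tapply(rate, list(uf, factor(stim$eye, levels = eyes),
                         factor(stim$orientation_deg, levels = orients)),
              mean)
  if (anyNA(R)) stop("incomplete design: every unit needs every eye x orientation")
  bRate <- tapply(blank$spike_count / blank$stim_s,
                  factor(blank$unit_id, levels = units), mean)
  if (anyNA(bRate)) stop("missing blank trials for unit(s): ",
                         paste(units[is.na(bRate)], collapse = ", "))
  evoked <- sweep(R, 1, bRate, "-")
  nU <- length(units)
  rawPref <- apply(R, 1, max)
  included <- ifelse(bRate > 0, rawPref >= 1.5 * bRate, rawPref > 0)
  if (responseAt == "global") {
    eMax <- pmax(evoked[, 1, , drop = TRUE], evoked[, 2, , drop = TRUE])
    if (nU == 1L) eMax <- matrix(eMax, nrow = 1L)
    prefIdx <- max.col(eMax, ties.method = "first")
    ce <- evoked[cbind(seq_len(nU), 1L, prefIdx)]
    ie <- evoked[cbind(seq_len(nU), 2L, prefIdx)]
  } else {
    eC <- evoked[, 1, , drop = TRUE]; eI <- evoked[, 2, , drop = TRUE]
    if (nU == 1L) { eC <- matrix(eC, nrow = 1L); eI <- matrix(eI, nrow = 1L) }
    ce <- eC[cbind(seq_len(nU), max.col(eC, ties.method = "first"))]
    ie <- eI[cbind(seq_len(nU), max.col(eI, ties.method = "first"))]
  }
  ce <- pmax(ce, 0); ie <- pmax(ie, 0)
  defined <- (ce + ie) > 0
  odi <- ifelse(defined, (ie - ce) / (ie + ce), NA_real_)
  category <- rep(NA_integer_, nU)
  category[defined] <- odiToCategory(odi[defined])
  mouse <- trials$mouse_id[match(units, trials$unit_id)]
  data.frame(mouse_id = mouse, unit_id = units, blank_hz = as.numeric(bRate),
             raw_pref_hz = rawPref, ce_hz = ce, ie_hz = ie, odi = odi,
             category = category, included = included & defined,
             stringsAsFactors = FALSE)
}

#' Orientation tuning from one unit's trials
#'
#' Computes mean stimulus-window firing rates per eye and orientation, the
#' blank-trial baseline rate, baseline-subtracted (evoked) rates, and the
#' preferred orientation per eye (argmax of the evoked rate; ties broken
#' toward the lowest orientation value).
#'
#' @param trials trial-table rows for a single unit (see [genODDataset()] for
#'   the column contract); blank trials must be present.
#' @param protocol the [StimProtocol-class] of the recording.
#' @return An [OrientationTuning-class].
#' @examples
#' sim <- genODDataset(stimProtocol(), odGroundTruth(), 1, 1, seed = 1)
#' tuningFromTrials(sim$trials, stimProtocol())
#' @export
tuningFromTrials <- function(trials, protocol) {
  .checkTrialTable(trials)
  if (length(unique(trials$unit_id)) != 1L)
    stop("tuningFromTrials expects trials from exactly one unit")
  eyes <- protocol@eyes
  orients <- protocolOrientations(protocol)
  stim <- trials[trials$eye != "blank", , drop = FALSE]
  blank <- trials[trials$eye == "blank", , drop = FALSE]
  if (!nrow(blank)) stop("missing blank trials: baseline rate undefined")
  raw <- tapply(stim$spike_count / stim$stim_s,
                list(factor(stim$eye, levels = eyes),
                     factor(stim$orientation_deg, levels = orients)), mean)
  if (anyNA(raw)) stop("incomplete design: every eye x orientation required")
  bRate <- mean(blank$spike_count / blank$stim_s)
  evoked <- raw - bRate
  prefIdx <- apply(evoked, 1, which.max)  # ties: first = lowest orientation
  prefDeg <- stats::setNames(orients[prefIdx], eyes)
  prefEvoked <- stats::setNames(evoked[cbind(seq_along(eyes), prefIdx)], eyes)
  new("OrientationTuning", unitId = as.character(trials$unit_id[1]),
      orientationsDeg = orients, rawRateHz = raw, blankRateHz = bRate,
      evokedRateHz = evoked, preferredDeg = prefDeg,
      preferredEvokedHz = prefEvoked)
}

#' Inclusion rule for visually responsive units
#'
#' A unit is included when its raw (not baseline-subtracted) firing rate at
#' the preferred orientation of its best eye is at least 50% greater than the
#' blank-trial rate, i.e. raw preferred rate >= 1.5 x blank rate. When the
#' blank rate is zero, any positive preferred-orientation rate passes.
#'
#' @param tuning An [OrientationTuning-class].
#' @return Logical flag.
#' @examples
#' # preferred 3.1 Hz vs blank 2.0 Hz -> 1.55x -> included
#' @export
passesInclusion <- function(tuning) {
  stopifnot(is(tuning, "OrientationTuning"))
  rawPref <- max(tuning@rawRateHz)
  if (tuning@blankRateHz > 0) rawPref >= 1.5 * tuning@blankRateHz
  else rawPref > 0
}

#' Ocular dominance index
#'
#' ODI = (IE - CE)/(IE + CE), where CE and IE are the responses through the
#' contralateral and ipsilateral eye. -1 is purely contralateral, +1 purely
#' ipsilateral. Vectorized.
#'
#' @param ce contralateral-eye response, Hz (>= 0).
#' @param ie ipsilateral-eye response, Hz (>= 0).
#' @return ODI in \[-1, 1\].
#' @examples
#' computeODI(10, 0)  # -1
#' computeODI(3, 7)   # 0.4
#' @export
computeODI <- function(ce, ie) {
  if (any(ce < 0) || any(ie < 0)) stop("responses must be >= 0")
  if (any(ce + ie == 0))
    stop("undefined response: CE + IE = 0 (unit should have been excluded)")
  (ie - ce) / (ie + ce)
}

.odiEdges <- c(-1, -0.75, -0.45, -0.15, 0.15, 0.45, 0.75, 1)

#' Seven-category ocular-dominance scheme
#'
#' Maps ODI to the seven-category scheme with edges -1, -0.75, -0.45, -0.15,
#' 0.15, 0.45, 0.75, 1. Bins are half-open \[lower, upper); the last bin is
#' closed at 1. Category 1 is purely contralateral, 7 purely ipsilateral.
#' Vectorized.
#'
#' @param odi ODI values in \[-1, 1\].
#' @return Integer categories 1..7.
#' @examples
#' odiToCategory(c(-1, 0.4, -0.75))  # 1, 5, 2
#' @export
odiToCategory <- function(odi) {
  if (any(is.na(odi)) || any(odi < -1 | odi > 1))
    stop("odi must lie in [-1, 1]")
  as.integer(findInterval(odi, .odiEdges, rightmost.closed = TRUE))
}

#' Contralateral bias index
#'
#' CBI = \[(n1 - n7) + (2/3)(n2 - n6) + (1/3)(n3 - n5) + N\] / 2N, where nx is
#' the number of units in ocular-dominance category x and N their total.
#' 1 = fully contralateral (all category 1), 0 = fully ipsilateral.
#'
#' @param counts numeric vector of length 7, category counts n1..n7.
#' @return CBI in \[0, 1\].
#' @examples
#' computeCBI(c(20, 0, 0, 0, 0, 0, 0))  # 1
#' computeCBI(c(0, 0, 0, 20, 0, 0, 0))  # 0.5
#' @export
computeCBI <- function(counts) {
  if (length(counts) != 7L) stop("counts must have length 7 (n1..n7)")
  if (any(counts < 0)) stop("counts must be >= 0")
  n <- sum(counts)
  if (n == 0) stop("empty summary: no included units (N = 0)")
  ((counts[1] - counts[7]) + (2 / 3) * (counts[2] - counts[6]) +
      (1 / 3) * (counts[3] - counts[5]) + n) / (2 * n)
}

#' Per-mouse ocular-dominance summaries
#'
#' Runs the unit chain (tuning, inclusion, ODI, category) over a trial table
#' and tallies the seven-category counts and CBI per mouse.
#'
#' @param trials trial table covering one or more mice.
#' @param protocol the [StimProtocol-class].
#' @param responseAt "global" (default): CE/IE at the unit's best orientation
#'   over both eyes; "pereye": at each eye's own preferred orientation.
#' @return A list with \code{units} (per-unit data.frame) and \code{mice}
#'   (per-mouse data.frame with columns \code{mouse_id, n1..n7, N, cbi};
#'   mice with no included units are omitted).
#' @export
mouseODSummary <- function(trials, protocol, responseAt = "global") {
  ut <- .odUnitTable(trials, protocol, responseAt)
  inc <- ut[ut$included, , drop = FALSE]
  mice <- sort(unique(ut$mouse_id))
  rows <- lapply(mice, function(m) {
    cats <- inc$category[inc$mouse_id == m]
    if (!length(cats)) return(NULL)
    n <- tabulate(cats, nbins = 7L)
    data.frame(mouse_id = m, t(stats::setNames(n, paste0("n", 1:7))),
               N = sum(n), cbi = computeCBI(n), stringsAsFactors = FALSE)
  })
  list(units = ut, mice = do.call(rbind, rows))
}

#' Group analysis of ocular-dominance plasticity
#'
#' Runs the full per-unit chain for a non-deprived (ND) and a monocularly
#' deprived (MD) condition, pools the per-unit ODI within condition for a
#' two-sample Kolmogorov-Smirnov comparison of the cumulative distributions,
#' compares per-mouse CBI by two-sample t test, and tabulates the
#' seven-category histograms. Mice whose units are all excluded are dropped
#' from the CBI comparison with a warning and recorded in the result.
#'
#' @param ndTrials trial table (or list of per-mouse tables) for the ND
#'   condition.
#' @param mdTrials trial table (or list of per-mouse tables) for the MD
#'   condition.
#' @param protocol the [StimProtocol-class].
#' @param responseAt see [mouseODSummary()].
#' @return An [ODGroupResult-class].
#' @examples
#' nd <- genODDataset(stimProtocol(), odGroundTruth(), 10, 3, seed = 1)
#' md <- genODDataset(stimProtocol(), odGroundTruth(mdShift = 0.5), 10, 3,
#'                    seed = 2)
#' odGroupAnalysis(nd$trials, md$trials, stimProtocol())
#' @export
odGroupAnalysis <- function(ndTrials, mdTrials, protocol,
                            responseAt = "global") {
  bindIf <- function(x) if (is.data.frame(x)) x else do.call(rbind, x)
  nd <- mouseODSummary(bindIf(ndTrials), protocol, responseAt)
  md <- mouseODSummary(bindIf(mdTrials), protocol, responseAt)
  if (is.null(nd$mice) || is.null(md$mice))
    stop("a condition has no mouse with included units")
  nd$units$condition <- "ND"; md$units$condition <- "MD"
  nd$mice$condition <- "ND"; md$mice$condition <- "MD"
  dropped <- c(setdiff(unique(nd$units$mouse_id), nd$mice$mouse_id),
               setdiff(unique(md$units$mouse_id), md$mice$mouse_id))
  if (length(dropped))
    warning("mice dropped (no included units): ",
            paste(dropped, collapse = ", "))
  odiND <- nd$units$odi[nd$units$included]
  odiMD <- md$units$odi[md$units$included]
  ks <- ksTwoSample(odiND, odiMD)
  cbi <- tTestGroups(nd$mice$cbi, md$mice$cbi, method = "pooled")
  hist <- rbind(ND = colSums(nd$mice[paste0("n", 1:7)]),
                MD = colSums(md$mice[paste0("n", 1:7)]))
  new("ODGroupResult",
      unitResults = rbind(nd$units, md$units),
      mouseSummaries = rbind(nd$mice, md$mice),
      ksTest = ks, cbiTest = cbi, categoryHistogram = hist,
      droppedMice = as.character(dropped))
}
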