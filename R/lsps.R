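# Excitatory/inhibitory input maps from grid photostimulation recordings:
# per-site response classification, map construction with direct-response
# exclusion, map averaging, and laminar input profiles.

#' Laminar input profile
#'
#' Mean synaptic input strength binned by cortical depth, with the combined
#' layer strengths used for group comparisons (L2/3 for excitatory maps,
#' L2/3 + L5 for inhibitory).
#'
#' @slot binEdgesUm depth-bin edges, um from pia.
#' @slot binLabels layer label per bin.
#' @slot binMeanPa per-bin mean input strength, pA (NaN where a bin holds no
#'   contributing sites).
#' @slot binN contributing sites per bin.
#' @slot combinedPa named numeric: \code{L23} mean over L2/3 sites and
#'   \code{L23L5} mean over L2/3 plus L5 sites.
#' @export
setClass("LaminarProfile", representation(
  binEdgesUm = "numeric", binLabels = "character", binMeanPa = "numeric",
  binN = "integer", combinedPa = "numeric"
))

setMethod("show", "LaminarProfile", function(object) {
  cat("LaminarProfile (mean input, pA):\n")
  for (i in seq_along(object@binLabels))
    cat(sprintf("  %-4s %4g-%4g um: %8.2f (n = %d)\n", object@binLabels[i],
                object@binEdgesUm[i], object@binEdgesUm[i + 1],
                object@binMeanPa[i], object@binN[i]))
  cat(sprintf("  combined L2/3: %.2f pA; L2/3+L5: %.2f pA\n",
              object@combinedPa["L23"], object@combinedPa["L23L5"]))
})

# sides = 2: centered (symmetric) smoothing, for peak localisation;
# sides = 1: causal smoothing, for onset-latency classification (a causal
# filter can only delay an onset, never pull it into an earlier window).
.boxcarSmooth <- function(x, k, sides = 2) {
  if (k <= 1L) return(x)
  y <- as.numeric(stats::filter(x, rep(1 / k, k), sides = sides))
  y[is.na(y)] <- x[is.na(y)]
  y
}

#' Classify one stimulation-site response
#'
#' A site is "direct" when the first deflection exceeding the detection
#' threshold begins within the direct window after laser onset (glutamate
#' acting on the recorded cell itself has near-zero synaptic latency);
#' "synaptic" when the first deflection begins within the synaptic window;
#' "none" otherwise. The detection threshold defaults to 3 x the robust RMS
#' (1.4826 MAD) of the pre-laser baseline. The site amplitude is the
#' baseline-subtracted mean current over the synaptic window (signed;
#' 0 for "none"), or the extremum when \code{estimator = "peak"}. Sweeps that
#' saturate the digitizer range are flagged "excluded".
#'
#' @param sweep a [TraceSweep-class] with a \code{laserOnsetS} annotation.
#' @param windowsMs two latencies (ms after laser onset): end of the direct
#'   window and end of the synaptic window; default c(7, 50).
#' @param thresholdPa detection threshold, pA; default \code{NULL} = 3 x
#'   baseline robust RMS.
#' @param thresholdSd multiplier for the RMS-derived threshold (default 3).
#' @param estimator "mean" (default) or "peak" amplitude estimator over the
#'   synaptic window.
#' @param smoothMs boxcar width for detection smoothing, ms (default 1).
#' @param saturationPa absolute current treated as digitizer saturation
#'   (default 4000).
#' @return A list with \code{class} ("direct", "synaptic", "none" or
#'   "excluded"), \code{amplitudePa}, and \code{onsetMs} (first-crossing
#'   latency, NA for none/excluded).
#' @export
classifySite <- function(sweep, windowsMs = c(7, 50), thresholdPa = NULL,
                         thresholdSd = 3, estimator = c("mean", "peak"),
                         smoothMs = 1, saturationPa = 4000) {
  stopifnot(is(sweep, "TraceSweep"))
  estimator <- match.arg(estimator)
  on <- sweep@annotations$laserOnsetS
  if (is.null(on)) stop("laser-onset annotation missing")
  if (windowsMs[2] <= windowsMs[1]) stop("windows must be ordered")
  fs <- sweep@samplingRateHz
  x <- sweep@samples
  if (any(abs(x) >= saturationPa))
    return(list(class = "excluded", amplitudePa = NA_real_, onsetMs = NA_real_))
  iOn <- round(on * fs)
  base <- x[seq_len(max(1L, iOn))]
  x0 <- x - stats::median(base)
  if (is.null(thresholdPa)) {
    rms <- stats::mad(base)
    thresholdPa <- thresholdSd * rms
  }
  sm <- .boxcarSmooth(x0, max(1L, round(smoothMs / 1000 * fs)), sides = 1)
  iD <- iOn + round(windowsMs[1] / 1000 * fs)
  iS <- min(length(x), iOn + round(windowsMs[2] / 1000 * fs))
  post <- (iOn + 1L):iS
  over <- post[abs(sm[post]) > thresholdPa]
  synWin <- (iD + 1L):iS
  if (!length(over)) {
    return(list(class = "none", amplitudePa = 0, onsetMs = NA_real_))
  }
  first <- over[1]
  cls <- if (first <= iD) "direct" else "synaptic"
  amp <- if (estimator == "mean") mean(x0[synWin])
  else x0[synWin][which.max(abs(x0[synWin]))]
  list(class = cls, amplitudePa = amp, onsetMs = (first - iOn) * 1000 / fs)
}

#' Build a synaptic input map from one LSPS recording
#'
#' Classifies every stimulation site of the recording and assembles the
#' per-site classes and amplitudes into grid-shaped matrices. Sites with
#' direct somatic responses are marked "direct" and excluded from synaptic
#' statistics (their amplitude is NA); synaptic amplitudes are clipped to the
#' mode's sign (excitatory <= 0, inhibitory >= 0).
#'
#' @param rec an [LSPSRecording-class].
#' @param mode "excitatory" or "inhibitory"; must match the holding potential
#'   (-70 mV excitatory, 0 mV inhibitory).
#' @param ... further arguments passed to [classifySite()].
#' @return An [InputMap-class].
#' @examples
#' sim <- genLSPSDataset(lspsGrid(), c(L1 = 0, L23 = -50, L4 = 0, L5 = -20,
#'                       L6 = 0), nCells = 1, seed = 1)
#' buildInputMap(sim$recordings[[1]], "excitatory")
#' @export
buildInputMap <- function(rec, mode = c("excitatory", "inhibitory"), ...) {
  stopifnot(is(rec, "LSPSRecording"))
  mode <- match.arg(mode)
  expected <- if (mode == "excitatory") -70 else 0
  if (!isTRUE(all.equal(rec@holdingMv, expected)))
    stop(sprintf("holding %g mV does not match %s mode (expected %g mV)",
                 rec@holdingMv, mode, expected))
  g <- rec@grid
  cls <- matrix("none", g@rows, g@cols)
  amp <- matrix(0, g@rows, g@cols)
  for (r in seq_len(g@rows)) {
    for (cl in seq_len(g@cols)) {
      s <- (r - 1L) * g@cols + cl
      res <- classifySite(rec@sweeps[[s]], ...)
      cls[r, cl] <- res$class
      amp[r, cl] <- switch(res$class,
        synaptic = if (mode == "excitatory") min(res$amplitudePa, 0)
                   else max(res$amplitudePa, 0),
        none = 0, NA_real_)
    }
  }
  new("InputMap", grid = g, mode = mode, classes = cls, amplitudesPa = amp)
}

#' Average input maps across cells
#'
#' Per-site mean over maps in which the site is synaptic or "none"; sites
#' classified direct or excluded in a given map do not contribute to that
#' site's mean or n. Maps may be aligned by their pia row (default; the
#' recordings already share a pia-aligned grid) or re-centred on the soma.
#'
#' @param maps list of [InputMap-class] with identical grid geometry and mode.
#' @param alignment "pia-row" (default) or "soma-centered". Soma-centred
#'   alignment shifts each map by the integer row/column offset of its soma
#'   from the first map's soma before averaging; sites shifted outside the
#'   grid are dropped.
#' @return A list with \code{meanMap} (numeric matrix of per-site mean
#'   amplitude, NaN where no map contributes), \code{n} (integer matrix of
#'   contributing maps per site), \code{mode} and \code{grid}.
#' @export
averageMaps <- function(maps, alignment = c("pia-row", "soma-centered")) {
  alignment <- match.arg(alignment)
  if (!length(maps)) stop("at least one map required")
  stopifnot(all(vapply(maps, is, logical(1), "InputMap")))
  g <- maps[[1]]@grid
  mode <- maps[[1]]@mode
  for (m in maps) {
    if (m@grid@rows != g@rows || m@grid@cols != g@cols ||
        m@grid@spacingUm != g@spacingUm)
      stop("maps must share grid geometry")
    if (m@mode != mode) stop("mixed excitatory/inhibitory maps")
  }
  acc <- matrix(0, g@rows, g@cols)
  cnt <- matrix(0L, g@rows, g@cols)
  for (m in maps) {
    a <- m@amplitudesPa
    use <- m@classes %in% c("synaptic", "none")
    dim(use) <- dim(a)
    if (alignment == "soma-centered") {
      dr <- round(m@grid@somaRow - g@somaRow)
      dc <- round(m@grid@somaCol - g@somaCol)
      a <- .shiftMatrix(a, -dr, -dc)
      use <- .shiftMatrix(use, -dr, -dc, fill = FALSE)
      a[is.na(a) & use] <- NA
    }
    ok <- use & !is.na(a)
    acc[ok] <- acc[ok] + a[ok]
    cnt <- cnt + ok
  }
  meanMap <- acc / cnt  # 0/0 -> NaN where no map contributes
  list(meanMap = meanMap, n = cnt, mode = mode, grid = g)
}

.shiftMatrix <- function(m, dr, dc, fill = NA) {
  out <- matrix(fill, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)); cs <- seq_len(ncol(m))
  rOk <- rs - dr >= 1 & rs - dr <= nrow(m)
  cOk <- cs - dc >= 1 & cs - dc <= ncol(m)
  out[rs[rOk], cs[cOk]] <- m[rs[rOk] - dr, cs[cOk] - dc]
  out
}

#' Laminar profile of an input map
#'
#' Bins the map's sites by depth below the pia (site depth =
#' (row - 1) x spacing; the top row is aligned with the pia) and reports the
#' mean synaptic amplitude per depth bin, plus the combined L2/3 and
#' L2/3 + L5 strengths used for group comparisons. Direct/excluded sites do
#' not contribute; "none" sites contribute zeros. The map may also be the
#' \code{meanMap} matrix from [averageMaps()] (pass its grid).
#'
#' @param map an [InputMap-class], or a numeric matrix of site amplitudes.
#' @param layerBoundsUm named depth edges, um (default
#'   [defaultLayerBounds()]).
#' @param grid required when \code{map} is a bare matrix.
#' @return A [LaminarProfile-class]. Empty bins report n = 0 and NaN mean.
#' @export
laminarProfile <- function(map, layerBoundsUm = defaultLayerBounds(),
                           grid = NULL) {
  if (is(map, "InputMap")) {
    amp <- map@amplitudesPa
    keep <- map@classes %in% c("synaptic", "none")
    dim(keep) <- dim(amp)
    grid <- map@grid
  } else {
    if (is.null(grid)) stop("grid required when map is a matrix")
    amp <- map
    keep <- !is.na(amp)
  }
  depths <- gridRowDepthsUm(grid)
  if (min(depths) < min(layerBoundsUm) || max(depths) > max(layerBoundsUm))
    stop("layer bounds must cover the mapped depth range")
  rowBin <- findInterval(depths, layerBoundsUm, rightmost.closed = TRUE)
  labels <- names(layerBoundsUm)[-length(layerBoundsUm)]
  nBin <- length(labels)
  binMean <- rep(NaN, nBin)
  binN <- integer(nBin)
  siteBin <- matrix(rowBin, grid@rows, grid@cols)
  ok <- keep & !is.na(amp)
  for (b in seq_len(nBin)) {
    sel <- ok & siteBin == b
    binN[b] <- sum(sel)
    if (binN[b] > 0) binMean[b] <- mean(amp[sel])
  }
  comb <- c(
    L23 = if (any(ok & siteBin == match("L23", labels)))
      mean(amp[ok & siteBin == match("L23", labels)]) else NaN,
    L23L5 = {
      sel <- ok & (siteBin == match("L23", labels) |
                     siteBin == match("L5", labels))
      if (any(sel)) mean(amp[sel]) else NaN
    })
  new("LaminarProfile", binEdgesUm = as.numeric(layerBoundsUm),
      binLabels = labels, binMeanPa = binMean, binN = binN,
      combinedPa = comb)
}
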