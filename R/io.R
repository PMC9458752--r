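# Readers/writers for the fixture formats (trial-table CSV, trace bundles
# with a binary or CSV sample store, JSON truth files), declarative run
# configuration, and the seeded simulate-and-analyze pipeline.

.trialTableCols <- c("mouse_id", "unit_id", "eye", "orientation_deg",
                     "repeat", "spike_count", "stim_s", "trial_s")

.checkTrialTable <- function(trials) {
  if (!is.data.frame(trials)) stop("trial table must be a data.frame")
  missing <- setdiff(.trialTableCols, names(trials))
  if (length(missing))
    stop("trial table is missing required column(s): ",
         paste(missing, collapse = ", "))
  invisible(trials)
}

#' Read a trial table CSV
#'
#' Validates the column schema (\code{mouse_id, unit_id, eye,
#' orientation_deg, repeat, spike_count, stim_s, trial_s}) and the eye
#' labels; the row count of the file is preserved.
#'
#' @param path CSV path.
#' @param eyes permitted eye labels besides "blank" (default
#'   \code{c("contra", "ipsi")}).
#' @return The validated trial-table data.frame.
#' @export
readTrialTable <- function(path, eyes = c("contra", "ipsi")) {
  tt <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  .checkTrialTable(tt)
  bad <- setdiff(unique(tt$eye), c(eyes, "blank"))
  if (length(bad)) stop("unknown eye label: ", paste(bad, collapse = ", "))
  tt
}

#' Write a trial table CSV
#'
#' @param trials trial-table data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeTrialTable <- function(trials, path) {
  .checkTrialTable(trials)
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trace bundle
#'
#' A trace bundle is a directory with \code{meta.json} (sampling rate, units,
#' per-sweep lengths, annotations) plus the raw samples, either as
#' \code{samples.bin} (little-endian 32-bit floats, sweep-major) or as a CSV
#' fallback \code{samples.csv} (columns \code{sweep, time_s, value}).
#'
#' @param sweeps list of [TraceSweep-class].
#' @param path bundle directory (created if needed).
#' @param format "binary" (default) or "csv".
#' @return \code{path}, invisibly.
#' @export
writeTraceBundle <- function(sweeps, path, format = c("binary", "csv")) {
  format <- match.arg(format)
  stopifnot(all(vapply(sweeps, is, logical(1), "TraceSweep")))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format = format,
    sampling_rate_hz = sweeps[[1]]@samplingRateHz,
    units = sweeps[[1]]@units,
    sweep_lengths = vapply(sweeps, function(s) length(s@samples), integer(1)),
    baseline_window_s = lapply(sweeps, function(s) s@baselineWindowS),
    annotations = lapply(sweeps, function(s) s@annotations))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  allSamples <- unlist(lapply(sweeps, function(s) s@samples))
  if (format == "binary") {
    con <- file(file.path(path, "samples.bin"), "wb")
    on.exit(close(con))
    writeBin(as.numeric(allSamples), con, size = 4L, endian = "little")
  } else {
    fs <- sweeps[[1]]@samplingRateHz
    df <- do.call(rbind, lapply(seq_along(sweeps), function(k) {
      data.frame(sweep = k, time_s = sweepTimes(sweeps[[k]]),
                 value = sweeps[[k]]@samples)
    }))
    utils::write.csv(df, file.path(path, "samples.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a trace bundle
#'
#' Reads the bundle written by [writeTraceBundle()]; sample counts must match
#' the header exactly (a truncated sample store is a corruption error).
#' Binary samples are 32-bit floats, so round-tripping through a binary
#' bundle is exact only to single precision; the CSV store is read with full
#' printed precision.
#'
#' @param path bundle directory.
#' @return List of [TraceSweep-class].
#' @export
readTraceBundle <- function(path) {
  metaPath <- file.path(path, "meta.json")
  if (!file.exists(metaPath)) stop("meta.json not found in bundle: ", path)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  lens <- as.integer(meta$sweep_lengths)
  total <- sum(lens)
  binPath <- file.path(path, "samples.bin")
  csvPath <- file.path(path, "samples.csv")
  if (identical(meta$format, "binary") || file.exists(binPath)) {
    if (!file.exists(binPath)) stop("samples.bin not found in bundle: ", path)
    sz <- file.info(binPath)$size
    if (sz != 4 * total)
      stop("corrupt bundle: samples.bin holds ", sz %/% 4,
           " samples but header declares ", total)
    con <- file(binPath, "rb")
    on.exit(close(con))
    x <- readBin(con, "numeric", n = total, size = 4L, endian = "little")
  } else {
    if (!file.exists(csvPath)) stop("no sample store found in bundle: ", path)
    df <- utils::read.csv(csvPath)
    if (nrow(df) != total)
      stop("corrupt bundle: samples.csv holds ", nrow(df),
           " samples but header declares ", total)
    x <- df$value[order(df$sweep)]
  }
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ann <- meta$annotations
  bw <- meta$baseline_window_s
  lapply(seq_along(lens), function(k) {
    a <- if (is.data.frame(ann)) as.list(ann[k, , drop = FALSE])
    else as.list(ann[[k]])
    a <- a[!vapply(a, function(v) is.null(v) || all(is.na(v)), logical(1))]
    w <- if (is.list(bw)) as.numeric(bw[[k]]) else as.numeric(bw[k, ])
    traceSweep(x[starts[k]:ends[k]], meta$sampling_rate_hz,
               units = meta$units, baselineWindowS = w, annotations = a)
  })
}

#' Write ground truth to JSON
#'
#' Serializes a generator truth object ([ODGroundTruth-class] or
#' [MiniGroundTruth-class]) so that it reloads identically with
#' [readTruthJSON()].
#'
#' @param truth the truth object.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeTruthJSON <- function(truth, path) {
  cls <- class(truth)[1]
  slots <- slotNames(truth)
  payload <- c(list(.class = cls),
               stats::setNames(lapply(slots, function(s) slot(truth, s)),
                               slots))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read ground truth from JSON
#'
#' @param path JSON path written by [writeTruthJSON()].
#' @return The reconstructed truth object.
#' @export
readTruthJSON <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- p$.class
  p$.class <- NULL
  proto <- new(cls)
  for (s in slotNames(proto)) {
    v <- p[[s]]
    tgt <- class(slot(proto, s))
    if (tgt == "data.frame") v <- as.data.frame(v, stringsAsFactors = FALSE)
    if (tgt == "integer") v <- as.integer(v)
    if (tgt == "numeric") v <- as.numeric(v)
    if (is.null(v)) v <- slot(proto, s)
    slot(proto, s) <- v
  }
  validObject(proto)
  proto
}

.defaultConfig <- function() {
  list(
    seed = 1L,
    protocol = list(n_orientations = 12L, stim_duration_s = 2,
                    trial_duration_s = 4, repeats_per_condition = 3L),
    od = list(n_units = 30L, n_mice = 7L, baseline_rate_hz = 2,
              contra_drive_hz = 10, ipsi_drive_hz = 5, tuning_kappa = 4,
              drive_sdlog = 0.35, md_shift = 0.5, response_at = "global"),
    out_dir = NULL)
}

#' Read a run configuration
#'
#' A declarative YAML (or JSON) configuration layered over the documented
#' defaults; unknown keys are a validation error so that typos cannot
#' silently fall back to defaults.
#'
#' @param path YAML/JSON path, or NULL for the defaults.
#' @return Named configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- .defaultConfig()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                           simplifyVector = TRUE)
  else yaml::read_yaml(path)
  merge <- function(base, upd, prefix = "") {
    for (k in names(upd)) {
      if (!k %in% names(base))
        stop("unknown configuration key: ", prefix, k)
      if (is.list(base[[k]]) && is.list(upd[[k]]))
        base[[k]] <- merge(base[[k]], upd[[k]], paste0(prefix, k, "."))
      else base[[k]] <- upd[[k]]
    }
    base
  }
  merge(cfg, user)
}

#' Run the simulate-and-analyze ocular-dominance pipeline
#'
#' Executes the configured stages: simulate an ND and an MD cohort with the
#' configured population parameters, run the full ocular-dominance analysis
#' chain, and (optionally) write per-unit, per-mouse and group outputs under
#' \code{config$out_dir} as CSV/JSON. Re-running with the same configuration
#' reproduces identical outputs: all randomness is seeded from
#' \code{config$seed}.
#'
#' @param config configuration list from [readRunConfig()] (or NULL for the
#'   defaults).
#' @return A run report: list with \code{config}, \code{result} (an
#'   [ODGroupResult-class]), \code{warnings}, \code{outputs} (paths written),
#'   \code{version}, \code{timestamp}.
#' @examples
#' rep <- runPipeline()
#' rep$result
#' @export
runPipeline <- function(config = NULL) {
  if (is.null(config)) config <- .defaultConfig()
  pr <- config$protocol
  protocol <- stimProtocol(nOrientations = pr$n_orientations,
                           stimDurationS = pr$stim_duration_s,
                           trialDurationS = pr$trial_duration_s,
                           repeatsPerCondition = pr$repeats_per_condition)
  od <- config$od
  truthND <- odGroundTruth(contraDriveHz = od$contra_drive_hz,
                           ipsiDriveHz = od$ipsi_drive_hz,
                           baselineRateHz = od$baseline_rate_hz,
                           tuningKappa = od$tuning_kappa,
                           mdShift = 0, driveSdLog = od$drive_sdlog)
  truthMD <- odGroundTruth(contraDriveHz = od$contra_drive_hz,
                           ipsiDriveHz = od$ipsi_drive_hz,
                           baselineRateHz = od$baseline_rate_hz,
                           tuningKappa = od$tuning_kappa,
                           mdShift = od$md_shift, driveSdLog = od$drive_sdlog)
  seed <- as.integer(config$seed)
  nd <- genODDataset(protocol, truthND, od$n_units, od$n_mice, seed = seed)
  md <- genODDataset(protocol, truthMD, od$n_units, od$n_mice,
                     seed = seed + 1L)
  warnings <- character()
  result <- withCallingHandlers(
    odGroupAnalysis(nd$trials, md$trials, protocol,
                    responseAt = od$response_at),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  outputs <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    unitsCsv <- file.path(config$out_dir, "units.csv")
    miceCsv <- file.path(config$out_dir, "mice.csv")
    groupJson <- file.path(config$out_dir, "group.json")
    utils::write.csv(result@unitResults, unitsCsv, row.names = FALSE)
    utils::write.csv(result@mouseSummaries, miceCsv, row.names = FALSE)
    jsonlite::write_json(list(
      ks = list(D = result@ksTest@statistic, p = result@ksTest@p),
      cbi_t = list(t = result@cbiTest@statistic, df = result@cbiTest@df,
                   p = result@cbiTest@p),
      category_histogram = result@categoryHistogram,
      dropped_mice = result@droppedMice,
      config = config), groupJson, auto_unbox = TRUE, digits = NA)
    outputs <- c(unitsCsv, miceCsv, groupJson)
  }
  list(config = config, result = result, warnings = warnings,
       outputs = outputs,
       version = as.character(utils::packageVersion("CircuitPlasticity")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
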