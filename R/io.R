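## ---- EpochSet container: CSV of samples + JSON sidecar ----

conditionToList <- function(cond) {
  list(ear = cond@ear, kind = cond@kind, frequency = cond@frequency,
       level = cond@level, itd = cond@itd)
}

conditionFromList <- function(x) {
  stimulusCondition(ear = x$ear, kind = x$kind,
                    frequency = if (is.null(x$frequency)) NA else x$frequency,
                    level = x$level,
                    itd = if (is.null(x$itd)) NA else x$itd)
}

#' Write an epoch set to disk
#'
#' Samples go to `<basename>.csv` (epochs in rows, full precision); sampling
#' rate, stimulus condition, animal id and seed go to a `<basename>.json`
#' sidecar.
#'
#' @param epochs an [EpochSet-class].
#' @param basename path without extension.
#' @return invisibly, the two file paths.
#' @export
writeEpochSet <- function(epochs, basename) {
  stopifnot(is(epochs, "EpochSet"))
  csv <- paste0(basename, ".csv")
  js <- paste0(basename, ".json")
  utils::write.table(format(epochs@samples, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     csv, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(fs = epochs@fs, condition = conditionToList(epochs@condition),
               animalId = epochs@animalId,
               seed = if (length(epochs@seed)) epochs@seed else NULL,
               nEpochs = nrow(epochs@samples), nSamples = ncol(epochs@samples))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(c(csv = csv, json = js))
}

#' Read an epoch set written by [writeEpochSet()]
#'
#' @param basename path without extension.
#' @return an [EpochSet-class].
#' @export
readEpochSet <- function(basename) {
  csv <- paste0(basename, ".csv")
  js <- paste0(basename, ".json")
  if (!file.exists(csv) || !file.exists(js))
    stop("epoch set container not found: ", basename)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  m <- tryCatch(
    as.matrix(utils::read.table(csv, sep = ",", header = FALSE,
                                colClasses = "numeric")),
    warning = function(w) stop("corrupt epoch samples in ", csv, ": ",
                               conditionMessage(w)),
    error = function(e) stop("corrupt epoch samples in ", csv, ": ",
                             conditionMessage(e)))
  dimnames(m) <- NULL
  if (!is.null(meta$nSamples) && ncol(m) != meta$nSamples)
    stop("corrupt epoch set: sample count does not match sidecar")
  new("EpochSet", samples = m, fs = meta$fs,
      condition = conditionFromList(meta$condition),
      animalId = meta$animalId %||% "",
      seed = if (is.null(meta$seed)) integer(0) else as.integer(meta$seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- tidy CSV exports ----

#' Write peak sets as tidy CSV
#'
#' Columns: animal, ear, wave, amplitude_uV, latency_ms, present.
#'
#' @param peakSets list of [PeakSet-class] (or a single one).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writePeakCsv <- function(peakSets, path) {
  if (is(peakSets, "PeakSet")) peakSets <- list(peakSets)
  tab <- peakFeatureTable(peakSets)
  utils::write.csv(tab[, c("animal", "ear", "wave", "amplitude_uV",
                           "latency_ms", "present")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a DN1 curve as tidy CSV
#'
#' Columns: animal, itd_ms, dn1_amplitude_uV, dn1_latency_ms, present.
#'
#' @param curve a [BICCurve-class].
#' @param path output CSV path.
#' @param animalId provenance tag.
#' @return invisibly, `path`.
#' @export
writeBicCsv <- function(curve, path, animalId = "") {
  m <- curve@measures
  utils::write.csv(data.frame(animal = animalId, itd_ms = m$itd,
                              dn1_amplitude_uV = m$amplitude,
                              dn1_latency_ms = m$latency,
                              present = m$present),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write an audiogram as tidy CSV
#'
#' Columns: animal, frequency_khz, threshold_db_spl, censored.
#'
#' @param audiogram an [Audiogram-class].
#' @param path output CSV path.
#' @param animalId provenance tag.
#' @return invisibly, `path`.
#' @export
writeAudiogramCsv <- function(audiogram, path, animalId = "") {
  utils::write.csv(audiogramTable(audiogram, animalId), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a cue set as tidy CSVs
#'
#' `<basename>_spectra.csv` holds the long-format gain/DTF/ILD spectra and
#' `<basename>_itd.csv` the per-azimuth ITD table.
#'
#' @param cues a [CueSet-class].
#' @param basename path without suffix.
#' @return invisibly, the two file paths.
#' @export
writeCueCsv <- function(cues, basename) {
  sp <- paste0(basename, "_spectra.csv")
  it <- paste0(basename, "_itd.csv")
  utils::write.csv(cueTable(cues), sp, row.names = FALSE)
  utils::write.csv(itdTable(cues), it, row.names = FALSE)
  invisible(c(spectra = sp, itd = it))
}

## ---- WAV (RIFF) support: IEEE float32 write, float32/PCM16 read ----

#' Write samples as a WAV file (IEEE float PCM)
#'
#' Minimal RIFF/WAVE writer for 32-bit IEEE float samples; channels are the
#' columns of a matrix (a vector is one channel).
#'
#' @param samples numeric vector or matrix (samples x channels), full scale
#'   +/- 1.
#' @param path output path.
#' @param fs sampling rate, Hz.
#' @return invisibly, `path`.
#' @export
writeWav <- function(samples, path, fs) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  nch <- ncol(samples)
  n <- nrow(samples)
  bytesPerSample <- 4L
  dataBytes <- n * nch * bytesPerSample
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataBytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")       # IEEE float
  writeBin(nch, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * nch * bytesPerSample), con, size = 4,
           endian = "little")
  writeBin(as.integer(nch * bytesPerSample), con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataBytes, con, size = 4, endian = "little")
  interleaved <- as.numeric(t(samples))
  writeBin(interleaved, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a WAV file written with [writeWav()] (or integer PCM16)
#'
#' @param path input path.
#' @return list with `samples` (matrix, samples x channels) and `fs` (Hz).
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!nzchar(id)) stop("no data chunk found in ", path)
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        code = readBin(con, "integer", size = 2, endian = "little"),
        nch = readBin(con, "integer", size = 2, endian = "little"),
        fs = readBin(con, "integer", size = 4, endian = "little"))
      readBin(con, "raw", n = size - 8)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      if (fmt$code == 3L) {
        x <- readBin(con, "numeric", n = size / 4, size = 4,
                     endian = "little")
      } else if (fmt$code == 1L) {
        x <- readBin(con, "integer", n = size / 2, size = 2, signed = TRUE,
                     endian = "little") / 32768
      } else stop("unsupported WAV format code: ", fmt$code)
      m <- matrix(x, ncol = fmt$nch, byrow = TRUE)
      return(list(samples = m, fs = fmt$fs))
    } else {
      readBin(con, "raw", n = size)
    }
  }
}

## ---- generator configuration as YAML ----

#' Write a generator configuration as YAML
#'
#' The growth function is stored by name (`"linear"` for [linearGrowth()];
#' custom functions are not serializable and are rejected).
#'
#' @param config an [ABRSimConfig-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeSimConfig <- function(config, path) {
  stopifnot(is(config, "ABRSimConfig"))
  growthName <- if (identical(config@growth, linearGrowth)) "linear" else
    stop("only the built-in linear growth function is serializable")
  x <- list(
    waveParams = as.list(config@waveParams),
    waveWidth = config@waveWidth,
    noiseSd = config@noiseSd,
    nEpochs = config@nEpochs,
    epochDur = config@epochDur,
    fs = config@fs,
    growth = growthName,
    trueThreshold = config@trueThreshold,
    bicParams = as.list(config@bicParams),
    dn1Width = config@dn1Width,
    seed = config@seed)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read a generator configuration written by [writeSimConfig()]
#'
#' @param path YAML path.
#' @return an [ABRSimConfig-class].
#' @export
readSimConfig <- function(path) {
  x <- yaml::read_yaml(path)
  growth <- switch(x$growth, linear = linearGrowth,
                   stop("unknown growth function: ", x$growth))
  new("ABRSimConfig",
      waveParams = as.data.frame(x$waveParams),
      waveWidth = as.numeric(x$waveWidth),
      noiseSd = x$noiseSd, nEpochs = as.integer(x$nEpochs),
      epochDur = x$epochDur, fs = x$fs, growth = growth,
      trueThreshold = x$trueThreshold,
      bicParams = as.data.frame(x$bicParams),
      dn1Width = x$dn1Width, seed = as.integer(x$seed))
}
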