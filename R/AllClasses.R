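#' @import methods
NULL

## Tone frequencies used throughout (kHz). Click stimuli carry frequency NA.
.TONE_FREQS <- c(1, 2, 4, 8, 16, 24, 32, 46)

## ITD grid for binaural click stimulation (ms).
.ITD_GRID <- seq(-2, 2, by = 0.5)

#' Stimulus condition descriptor
#'
#' Describes one stimulation condition: which ear(s) were driven, the stimulus
#' kind (transient click or tone pip), the tone frequency, the presentation
#' level, and -- for binaural stimulation -- the interaural time difference.
#'
#' @slot ear character, one of `"left"`, `"right"`, `"binaural"`.
#' @slot kind character, `"click"` or `"tone"`.
#' @slot frequency numeric, tone frequency in kHz (one of 1, 2, 4, 8, 16, 24,
#'   32, 46); `NA` for clicks.
#' @slot level numeric, presentation level in dB SPL.
#' @slot itd numeric, interaural time difference in ms on the
#'   -2..+2 ms, 0.5 ms grid; `NA` unless `ear == "binaural"`.
#' @exportClass StimulusCondition
setClass("StimulusCondition",
  representation(ear = "character", kind = "character",
                 frequency = "numeric", level = "numeric", itd = "numeric"),
  prototype(ear = "left", kind = "click", frequency = NA_real_,
            level = 90, itd = NA_real_))

setValidity("StimulusCondition", function(object) {
  msg <- character()
  if (!object@ear %in% c("left", "right", "binaural"))
    msg <- c(msg, "ear must be 'left', 'right' or 'binaural'")
  if (!object@kind %in% c("click", "tone"))
    msg <- c(msg, "kind must be 'click' or 'tone'")
  if (object@kind == "tone" &&
      (is.na(object@frequency) || !object@frequency %in% .TONE_FREQS))
    msg <- c(msg, sprintf("tone frequency must be one of %s kHz",
                          paste(.TONE_FREQS, collapse = ", ")))
  if (object@ear == "binaural") {
    if (is.na(object@itd))
      msg <- c(msg, "binaural condition requires an itd")
    else if (abs(object@itd) > 2 ||
             min(abs(object@itd - .ITD_GRID)) > 1e-9)
      msg <- c(msg, "itd must lie on the -2..+2 ms grid in 0.5 ms steps")
  }
  if (length(msg)) msg else TRUE
})

#' ABR simulation configuration
#'
#' Parameters of the synthetic ABR generator: per-wave template means with
#' between-animal SDs, template widths, epoch noise, epoch geometry, a level
#' growth function, and the DN1 (binaural interaction) parameter table.
#'
#' @slot waveParams data.frame with columns `wave` (I..IV), `ampMean` (uV),
#'   `ampSd` (uV), `latMean` (ms), `latSd` (ms). Between-animal draws use the
#'   SD columns; templates use the means.
#' @slot waveWidth numeric(4), Gaussian template SD per wave in ms.
#' @slot noiseSd numeric, additive white noise SD per epoch (uV); the noise is
#'   broadband and is band-limited downstream by the 50-3000 Hz filter.
#' @slot nEpochs integer, epochs per condition.
#' @slot epochDur numeric, epoch duration in ms.
#' @slot fs numeric, sampling rate in Hz.
#' @slot growth function(level, threshold) -> amplitude scale in [0, 1].
#' @slot trueThreshold numeric, generating threshold in dB SPL used by the
#'   growth function for level series.
#' @slot bicParams data.frame with columns `itd` (ms), `ampMean`, `ampSd`
#'   (uV), `latMean`, `latSd` (ms) describing the injected DN1 deflection.
#' @slot dn1Width numeric, Gaussian SD of the injected DN1 deflection (ms).
#' @slot seed integer, base RNG seed.
#' @exportClass ABRSimConfig
setClass("ABRSimConfig",
  representation(waveParams = "data.frame", waveWidth = "numeric",
                 noiseSd = "numeric", nEpochs = "integer",
                 epochDur = "numeric", fs = "numeric", growth = "function",
                 trueThreshold = "numeric", bicParams = "data.frame",
                 dn1Width = "numeric", seed = "integer"))

setValidity("ABRSimConfig", function(object) {
  msg <- character()
  wp <- object@waveParams
  need <- c("wave", "ampMean", "ampSd", "latMean", "latSd")
  if (!all(need %in% names(wp)))
    msg <- c(msg, "waveParams must have columns wave, ampMean, ampSd, latMean, latSd")
  else {
    if (any(wp$ampMean < 0)) msg <- c(msg, "wave amplitudes must be >= 0")
    if (is.unsorted(wp$latMean, strictly = TRUE))
      msg <- c(msg, "wave latencies must be strictly increasing (I < II < III < IV)")
  }
  if (object@nEpochs < 1L) msg <- c(msg, "nEpochs must be >= 1")
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  if (object@epochDur <= 0) msg <- c(msg, "epochDur must be > 0")
  if (length(object@waveWidth) != nrow(wp) || any(object@waveWidth <= 0))
    msg <- c(msg, "waveWidth must be positive, one value per wave")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Set of stimulus-locked voltage epochs
#'
#' @slot samples numeric matrix, epochs in rows, samples in columns (uV).
#' @slot fs numeric, sampling rate (Hz).
#' @slot condition the [StimulusCondition-class] under which the epochs were
#'   acquired or simulated.
#' @slot animalId character identifier.
#' @slot seed integer, RNG seed used to generate the epochs (length 0 for
#'   recorded data).
#' @exportClass EpochSet
setClass("EpochSet",
  representation(samples = "matrix", fs = "numeric",
                 condition = "StimulusCondition", animalId = "character",
                 seed = "integer"))

setValidity("EpochSet", function(object) {
  msg <- character()
  if (!is.numeric(object@samples)) msg <- c(msg, "samples must be numeric")
  else if (!all(is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  if (nrow(object@samples) < 1L) msg <- c(msg, "at least one epoch required")
  if (length(msg)) msg else TRUE
})

#' Averaged, baseline-normalized voltage trace
#'
#' The pointwise mean across epochs with the full-trace mean subtracted, so
#' that peak and deflection amplitudes are read against a zero baseline.
#'
#' @slot values numeric, the trace (uV), mean zero to within 1e-9.
#' @slot fs numeric, sampling rate (Hz).
#' @slot condition the originating [StimulusCondition-class].
#' @slot baselineOffset numeric, the mean (uV) removed during normalization.
#' @exportClass AveragedTrace
setClass("AveragedTrace",
  representation(values = "numeric", fs = "numeric",
                 condition = "StimulusCondition", baselineOffset = "numeric"))

setValidity("AveragedTrace", function(object) {
  msg <- character()
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (length(object@values) &&
      abs(mean(object@values)) > 1e-9)
    msg <- c(msg, "trace must be baseline-normalized (mean zero within 1e-9)")
  if (length(msg)) msg else TRUE
})

#' Quantified ABR waves I-IV for one averaged trace
#'
#' Per wave: presence flag, the peak sample (time and value), the following
#' trough value, the peak-to-trough amplitude, and the latency (time to peak).
#'
#' @slot peaks data.frame with one row per wave (I..IV) and columns `wave`,
#'   `present`, `peakTime` (ms), `peakValue` (uV), `troughValue` (uV),
#'   `amplitude` (uV), `latency` (ms), `nEars` (1 for single-trace peak sets,
#'   1 or 2 after ear averaging).
#' @slot animalId,ear character provenance tags.
#' @exportClass PeakSet
setClass("PeakSet",
  representation(peaks = "data.frame", animalId = "character",
                 ear = "character"))

setValidity("PeakSet", function(object) {
  p <- object@peaks
  msg <- character()
  need <- c("wave", "present", "peakTime", "peakValue", "troughValue",
            "amplitude", "latency", "nEars")
  if (!all(need %in% names(p)))
    msg <- c(msg, paste("peaks must have columns:", paste(need, collapse = ", ")))
  else {
    pr <- p[p$present, , drop = FALSE]
    if (any(pr$amplitude < 0, na.rm = TRUE))
      msg <- c(msg, "amplitudes of present waves must be >= 0")
    if (nrow(pr) > 1 && is.unsorted(pr$latency, strictly = TRUE))
      msg <- c(msg, "latencies of present waves must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Manual annotation of detected peaks
#'
#' One action per wave: keep the automatic pick, move it to a new sample
#' index, or deselect the wave so it is not quantified.
#'
#' @slot actions data.frame with columns `wave`, `action` (one of `"keep"`,
#'   `"move"`, `"deselect"`) and `index` (1-based sample index, used only for
#'   `"move"`).
#' @exportClass AnnotationSet
setClass("AnnotationSet", representation(actions = "data.frame"))

setValidity("AnnotationSet", function(object) {
  a <- object@actions
  msg <- character()
  if (!all(c("wave", "action", "index") %in% names(a)))
    msg <- c(msg, "actions must have columns wave, action, index")
  else if (!all(a$action %in% c("keep", "move", "deselect")))
    msg <- c(msg, "action must be keep, move or deselect")
  if (length(msg)) msg else TRUE
})

#' Binaural interaction component trace
#'
#' BIC(t) = binaural(t) - [left(t) + right(t)], computed from three
#' baseline-normalized averaged traces at one ITD.
#'
#' @slot values numeric (uV).
#' @slot fs numeric (Hz).
#' @slot itd numeric (ms).
#' @slot provenance character, identifiers of the contributing traces.
#' @exportClass BICTrace
setClass("BICTrace",
  representation(values = "numeric", fs = "numeric", itd = "numeric",
                 provenance = "character"))

#' DN1 measurement at one ITD
#'
#' @slot amplitude numeric, magnitude of the DN1 deflection relative to the
#'   zero baseline (uV, >= 0).
#' @slot latency numeric, time of the deflection (ms).
#' @slot itd numeric (ms).
#' @slot present logical.
#' @exportClass BICMeasure
setClass("BICMeasure",
  representation(amplitude = "numeric", latency = "numeric", itd = "numeric",
                 present = "logical"))

setValidity("BICMeasure", function(object) {
  if (object@present && (!is.finite(object@amplitude) || object@amplitude < 0))
    "amplitude must be >= 0 when present" else TRUE
})

#' DN1 amplitude/latency across the ITD grid
#'
#' @slot measures data.frame with columns `itd` (ms), `amplitude` (uV),
#'   `latency` (ms), `present`, ordered by ITD.
#' @exportClass BICCurve
setClass("BICCurve", representation(measures = "data.frame"))

setValidity("BICCurve", function(object) {
  m <- object@measures
  msg <- character()
  if (!all(c("itd", "amplitude", "latency", "present") %in% names(m)))
    msg <- c(msg, "measures must have columns itd, amplitude, latency, present")
  else {
    if (anyDuplicated(m$itd)) msg <- c(msg, "itds must be unique")
    if (length(m$itd) && max(sapply(m$itd, function(x) min(abs(x - .ITD_GRID)))) > 1e-9)
      msg <- c(msg, "itds must lie on the -2..+2 ms, 0.5 ms grid")
  }
  if (length(msg)) msg else TRUE
})

#' Descending level series at one frequency (or click)
#'
#' @slot levels numeric, presentation levels in dB SPL, strictly descending in
#'   10 dB steps.
#' @slot traces list of [AveragedTrace-class], parallel to `levels`.
#' @slot label character, tone frequency in kHz as a string, or `"click"`.
#' @exportClass LevelSeries
setClass("LevelSeries",
  representation(levels = "numeric", traces = "list", label = "character"))

setValidity("LevelSeries", function(object) {
  msg <- character()
  if (length(object@levels) < 2L) msg <- c(msg, "at least two levels required")
  d <- diff(object@levels)
  if (length(d) && any(abs(d + 10) > 1e-9))
    msg <- c(msg, "levels must descend in exact 10 dB steps")
  if (length(object@traces) != length(object@levels))
    msg <- c(msg, "one trace per level required")
  if (length(msg)) msg else TRUE
})

#' Threshold estimate for one level series
#'
#' @slot threshold numeric, estimated threshold in dB SPL (the midpoint of the
#'   last level with a response and the first without); `NA` when censored.
#' @slot censored character, `"none"`, `"below_min"` (response at every tested
#'   level) or `"above_max"` (no response at any level).
#' @slot decisions data.frame with columns `level`, `present`, `score`.
#' @slot label character, frequency tag or `"click"`.
#' @exportClass ThresholdResult
setClass("ThresholdResult",
  representation(threshold = "numeric", censored = "character",
                 decisions = "data.frame", label = "character"),
  prototype(censored = "none", label = ""))

setValidity("ThresholdResult", function(object) {
  msg <- character()
  if (!object@censored %in% c("none", "below_min", "above_max"))
    msg <- c(msg, "censored must be none, below_min or above_max")
  if (object@censored == "none" && !is.finite(object@threshold))
    msg <- c(msg, "uncensored result requires a finite threshold")
  if (length(msg)) msg else TRUE
})

#' Audiogram: thresholds across tone frequencies
#'
#' @slot frequencies numeric, kHz, from the set 1, 2, 4, 8, 16, 24, 32, 46.
#' @slot results list of [ThresholdResult-class], parallel to `frequencies`.
#' @exportClass Audiogram
setClass("Audiogram",
  representation(frequencies = "numeric", results = "list"))

setValidity("Audiogram", function(object) {
  msg <- character()
  if (!length(object@frequencies)) msg <- c(msg, "audiogram must be non-empty")
  if (!all(object@frequencies %in% .TONE_FREQS))
    msg <- c(msg, "frequencies must come from the 1-46 kHz test set")
  if (anyDuplicated(object@frequencies)) msg <- c(msg, "duplicate frequencies")
  if (length(object@results) != length(object@frequencies))
    msg <- c(msg, "one result per frequency required")
  if (length(msg)) msg else TRUE
})

#' Rigid-head acoustic model
#'
#' Generates interaural delays by the sine-of-azimuth law with maximum delay
#' (pinna width + inter-pinna distance) / c, and a frequency-dependent head
#' shadow producing interaural level differences that approach `maxIldDb` at
#' lateral positions above the shadow corner frequency.
#'
#' @slot pinnaWidth,pinnaLength,interPinna numeric, mm.
#' @slot maxIldDb numeric, ILD reached at +/-90 deg well above the corner
#'   frequency (dB).
#' @slot shadowCornerHz numeric, corner frequency of the shadow high-pass
#'   shaping (Hz).
#' @slot soundSpeed numeric, m/s.
#' @exportClass HeadModel
setClass("HeadModel",
  representation(pinnaWidth = "numeric", pinnaLength = "numeric",
                 interPinna = "numeric", maxIldDb = "numeric",
                 shadowCornerHz = "numeric", soundSpeed = "numeric"))

setValidity("HeadModel", function(object) {
  msg <- character()
  if (any(c(object@pinnaWidth, object@pinnaLength, object@interPinna) <= 0))
    msg <- c(msg, "head dimensions must be positive")
  if (object@soundSpeed <= 0) msg <- c(msg, "sound speed must be positive")
  if (object@shadowCornerHz <= 0) msg <- c(msg, "shadow corner must be positive")
  if (length(msg)) msg else TRUE
})

#' Logarithmic swept-sine specification
#'
#' @slot fStart,fEnd numeric, sweep endpoint frequencies (Hz).
#' @slot fs numeric, sampling rate (Hz).
#' @slot nPoints integer, sweep length in samples (131072, i.e. "128k",
#'   by default; about 3 s at 44.1 kHz).
#' @slot levelDbfs numeric, peak level re full scale (dB).
#' @exportClass SweepSpec
setClass("SweepSpec",
  representation(fStart = "numeric", fEnd = "numeric", fs = "numeric",
                 nPoints = "integer", levelDbfs = "numeric"))

setValidity("SweepSpec", function(object) {
  msg <- character()
  if (object@fStart <= 0 || object@fStart >= object@fEnd)
    msg <- c(msg, "need 0 < fStart < fEnd")
  if (object@fEnd >= object@fs / 2)
    msg <- c(msg, "fEnd must be below the Nyquist frequency")
  if (object@nPoints < 2L) msg <- c(msg, "nPoints must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Two-ear sweep recordings over the horizontal speaker grid
#'
#' @slot azimuths numeric, degrees on the -90..+90, 10 deg grid (positive =
#'   right of the animal).
#' @slot left,right lists of numeric recordings, parallel to `azimuths`.
#' @slot calibration numeric, no-head (microphone only) recording.
#' @slot sweep the generating [SweepSpec-class].
#' @slot fs numeric (Hz).
#' @exportClass HRTFScene
setClass("HRTFScene",
  representation(azimuths = "numeric", left = "list", right = "list",
                 calibration = "numeric", sweep = "SweepSpec", fs = "numeric"))

setValidity("HRTFScene", function(object) {
  msg <- character()
  grid <- seq(-90, 90, by = 10)
  if (!all(object@azimuths %in% grid))
    msg <- c(msg, "azimuths must lie on the -90..+90 deg grid in 10 deg steps")
  if (length(object@left) != length(object@azimuths) ||
      length(object@right) != length(object@azimuths))
    msg <- c(msg, "one recording per ear per azimuth required")
  n <- unique(c(vapply(object@left, length, 1L),
                vapply(object@right, length, 1L), length(object@calibration)))
  if (length(n) > 1) msg <- c(msg, "all recordings must share one length")
  if (length(msg)) msg else TRUE
})

#' Impulse response recovered by sweep deconvolution
#'
#' @slot values numeric, impulse response; index 1 corresponds to lag 0.
#' @slot fs numeric (Hz).
#' @exportClass ImpulseResponse
setClass("ImpulseResponse",
  representation(values = "numeric", fs = "numeric"))

#' Gain spectrum on a fixed frequency grid
#'
#' @slot freq numeric, Hz.
#' @slot gainDb numeric, dB, parallel to `freq`.
#' @slot smoothing character, `"raw"` or a fractional-octave tag such as
#'   `"1/48 octave"`.
#' @slot nfft integer, FFT length used to compute the spectrum.
#' @exportClass GainSpectrum
setClass("GainSpectrum",
  representation(freq = "numeric", gainDb = "numeric",
                 smoothing = "character", nfft = "integer"),
  prototype(smoothing = "raw", nfft = 512L))

setValidity("GainSpectrum", function(object) {
  msg <- character()
  if (length(object@freq) != length(object@gainDb))
    msg <- c(msg, "freq and gainDb must have equal length")
  if (!all(is.finite(object@gainDb))) msg <- c(msg, "gains must be finite")
  if (length(msg)) msg else TRUE
})

#' Binaural cue set over the azimuth grid
#'
#' Per-azimuth HRTF gains per ear, directional transfer functions (DTFs),
#' interaural level difference spectra (right minus left, dB), and
#' cross-correlation interaural time differences (ms, positive = right ear
#' leads).
#'
#' @slot azimuths numeric, degrees.
#' @slot freq numeric, Hz.
#' @slot gainLeft,gainRight,dtfLeft,dtfRight,ild numeric matrices,
#'   frequencies in rows, azimuths in columns (dB).
#' @slot itdMs numeric, one ITD per azimuth (ms).
#' @exportClass CueSet
setClass("CueSet",
  representation(azimuths = "numeric", freq = "numeric",
                 gainLeft = "matrix", gainRight = "matrix",
                 dtfLeft = "matrix", dtfRight = "matrix", ild = "matrix",
                 itdMs = "numeric"))

setValidity("CueSet", function(object) {
  msg <- character()
  dims <- c(length(object@freq), length(object@azimuths))
  for (s in c("gainLeft", "gainRight", "dtfLeft", "dtfRight", "ild"))
    if (!identical(dim(slot(object, s)), as.integer(dims)))
      msg <- c(msg, sprintf("%s must be a %d x %d matrix", s, dims[1], dims[2]))
  if (length(object@itdMs) != length(object@azimuths))
    msg <- c(msg, "one ITD per azimuth required")
  if (length(msg)) msg else TRUE
})
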