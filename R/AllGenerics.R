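#' Sampling rate accessor
#'
#' @param x an object carrying a sampling rate.
#' @return numeric, Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "AveragedTrace", function(x) x@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "BICTrace", function(x) x@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "ImpulseResponse", function(x) x@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "HRTFScene", function(x) x@fs)

#' Voltage values accessor
#'
#' @param x an object carrying a voltage (or impulse response) series.
#' @return numeric vector.
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @rdname traceValues
#' @export
setMethod("traceValues", "AveragedTrace", function(x) x@values)
#' @rdname traceValues
#' @export
setMethod("traceValues", "BICTrace", function(x) x@values)
#' @rdname traceValues
#' @export
setMethod("traceValues", "ImpulseResponse", function(x) x@values)

#' Epoch matrix accessor
#'
#' @param x an [EpochSet-class].
#' @return numeric matrix, epochs in rows (uV).
#' @export
setGeneric("epochMatrix", function(x) standardGeneric("epochMatrix"))

#' @rdname epochMatrix
#' @export
setMethod("epochMatrix", "EpochSet", function(x) x@samples)

#' Number of epochs accessor
#'
#' @param x an [EpochSet-class].
#' @return integer.
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname nEpochs
#' @export
setMethod("nEpochs", "EpochSet", function(x) nrow(x@samples))

#' Stimulus condition accessor
#'
#' @param x an object acquired under a stimulus condition.
#' @return a [StimulusCondition-class].
#' @export
setGeneric("stimCondition", function(x) standardGeneric("stimCondition"))

#' @rdname stimCondition
#' @export
setMethod("stimCondition", "EpochSet", function(x) x@condition)
#' @rdname stimCondition
#' @export
setMethod("stimCondition", "AveragedTrace", function(x) x@condition)

#' Tidy peak table accessor
#'
#' @param x a [PeakSet-class].
#' @return data.frame, one row per wave.
#' @export
setGeneric("peakTable", function(x) standardGeneric("peakTable"))

#' @rdname peakTable
#' @export
setMethod("peakTable", "PeakSet", function(x) {
  cbind(animalId = x@animalId, ear = x@ear, x@peaks,
        stringsAsFactors = FALSE)
})

#' Tidy DN1 curve accessor
#'
#' @param x a [BICCurve-class].
#' @return data.frame with columns itd, amplitude, latency, present.
#' @export
setGeneric("bicTable", function(x) standardGeneric("bicTable"))

#' @rdname bicTable
#' @export
setMethod("bicTable", "BICCurve", function(x) x@measures)

#' Threshold value accessor
#'
#' @param x a [ThresholdResult-class] or [Audiogram-class].
#' @return numeric threshold(s) in dB SPL (`NA` when censored).
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))

#' @rdname thresholdValue
#' @export
setMethod("thresholdValue", "ThresholdResult", function(x) x@threshold)
#' @rdname thresholdValue
#' @export
setMethod("thresholdValue", "Audiogram", function(x) {
  setNames(vapply(x@results, function(r) r@threshold, numeric(1)),
           as.character(x@frequencies))
})

#' Azimuth grid accessor
#'
#' @param x an [HRTFScene-class] or [CueSet-class].
#' @return numeric, degrees.
#' @export
setGeneric("azimuths", function(x) standardGeneric("azimuths"))

#' @rdname azimuths
#' @export
setMethod("azimuths", "HRTFScene", function(x) x@azimuths)
#' @rdname azimuths
#' @export
setMethod("azimuths", "CueSet", function(x) x@azimuths)

#' Per-azimuth ITD table accessor
#'
#' @param x a [CueSet-class].
#' @return data.frame with columns azimuth_deg, itd_ms.
#' @export
setGeneric("itdTable", function(x) standardGeneric("itdTable"))

#' @rdname itdTable
#' @export
setMethod("itdTable", "CueSet", function(x) {
  data.frame(azimuth_deg = x@azimuths, itd_ms = x@itdMs)
})

#' Tidy cue spectra accessor
#'
#' @param x a [CueSet-class].
#' @return data.frame in long format with columns azimuth_deg, frequency_hz,
#'   gain_db_left, gain_db_right, dtf_db_left, dtf_db_right, ild_db.
#' @export
setGeneric("cueTable", function(x) standardGeneric("cueTable"))

#' @rdname cueTable
#' @export
setMethod("cueTable", "CueSet", function(x) {
  data.frame(
    azimuth_deg = rep(x@azimuths, each = length(x@freq)),
    frequency_hz = rep(x@freq, times = length(x@azimuths)),
    gain_db_left = as.vector(x@gainLeft),
    gain_db_right = as.vector(x@gainRight),
    dtf_db_left = as.vector(x@dtfLeft),
    dtf_db_right = as.vector(x@dtfRight),
    ild_db = as.vector(x@ild))
})
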