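setMethod("show", "StimulusCondition", function(object) {
  extra <- if (object@kind == "tone")
    sprintf(", %g kHz", object@frequency)
  else ""
  itd <- if (!is.na(object@itd)) sprintf(", itd %+g ms", object@itd) else ""
  cat(sprintf("StimulusCondition: %s %s%s, %g dB SPL%s\n",
              object@ear, object@kind, extra, object@level, itd))
})

setMethod("show", "ABRSimConfig", function(object) {
  cat(sprintf(paste0("ABRSimConfig: %d waves, %d epochs x %g ms @ %.2f Hz, ",
                     "noise %g uV, threshold %g dB SPL\n"),
              nrow(object@waveParams), object@nEpochs, object@epochDur,
              object@fs, object@noiseSd, object@trueThreshold))
  print(object@waveParams[, c("wave", "ampMean", "latMean")])
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet: %d epochs x %d samples @ %.2f Hz (%.1f ms)\n",
              nrow(object@samples), ncol(object@samples), object@fs,
              ncol(object@samples) / object@fs * 1000))
  show(object@condition)
})

setMethod("show", "AveragedTrace", function(object) {
  cat(sprintf(paste0("AveragedTrace: %d samples @ %.2f Hz, range ",
                     "[%.2f, %.2f] uV, baseline offset %.3g uV\n"),
              length(object@values), object@fs, min(object@values),
              max(object@values), object@baselineOffset))
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet (%s, ear %s):\n",
              if (nzchar(object@animalId)) object@animalId else "unnamed",
              if (nzchar(object@ear)) object@ear else "?"))
  p <- object@peaks
  print(data.frame(wave = p$wave, present = p$present,
                   amplitude_uV = round(p$amplitude, 3),
                   latency_ms = round(p$latency, 3)))
})

setMethod("show", "BICTrace", function(object) {
  cat(sprintf("BICTrace @ itd %+g ms: %d samples @ %.2f Hz, min %.2f uV\n",
              object@itd, length(object@values), object@fs,
              min(object@values)))
})

setMethod("show", "BICMeasure", function(object) {
  if (object@present)
    cat(sprintf("DN1 @ itd %+g ms: amplitude %.2f uV, latency %.2f ms\n",
                object@itd, object@amplitude, object@latency))
  else cat(sprintf("DN1 @ itd %+g ms: absent\n", object@itd))
})

setMethod("show", "BICCurve", function(object) {
  cat("BICCurve (DN1 across ITD):\n")
  m <- object@measures
  print(data.frame(itd_ms = m$itd, amplitude_uV = round(m$amplitude, 3),
                   latency_ms = round(m$latency, 3), present = m$present))
})

setMethod("show", "ThresholdResult", function(object) {
  lab <- if (nzchar(object@label)) paste0(" [", object@label, "]") else ""
  if (object@censored == "none")
    cat(sprintf("ThresholdResult%s: %.1f dB SPL\n", lab, object@threshold))
  else cat(sprintf("ThresholdResult%s: censored (%s)\n", lab,
                   object@censored))
})

setMethod("show", "Audiogram", function(object) {
  cat("Audiogram:\n")
  th <- thresholdValue(object)
  print(data.frame(frequency_khz = object@frequencies,
                   threshold_db_spl = unname(th),
                   censored = vapply(object@results,
                                     function(r) r@censored, character(1))))
})

setMethod("show", "HeadModel", function(object) {
  cat(sprintf(paste0("HeadModel: pinna %g x %g mm, inter-pinna %g mm, ",
                     "max ILD %g dB, max ITD %.1f us\n"),
              object@pinnaLength, object@pinnaWidth, object@interPinna,
              object@maxIldDb, predictMaxItd(object)))
})

setMethod("show", "SweepSpec", function(object) {
  cat(sprintf("SweepSpec: %g-%g Hz log sweep, %d samples @ %g Hz (%.2f s), %g dBfs\n",
              object@fStart, object@fEnd, object@nPoints, object@fs,
              sweepDuration(object), object@levelDbfs))
})

setMethod("show", "HRTFScene", function(object) {
  cat(sprintf("HRTFScene: %d azimuths (%g..%g deg), recordings %d samples @ %g Hz\n",
              length(object@azimuths), min(object@azimuths),
              max(object@azimuths), length(object@calibration), object@fs))
})

setMethod("show", "ImpulseResponse", function(object) {
  peak <- which.max(abs(object@values))
  cat(sprintf("ImpulseResponse: %d samples @ %g Hz, peak %.3g at %.3f ms\n",
              length(object@values), object@fs, object@values[peak],
              (peak - 1) / object@fs * 1000))
})

setMethod("show", "GainSpectrum", function(object) {
  cat(sprintf("GainSpectrum (%s, nfft %d): %d points, %.0f-%.0f Hz\n",
              object@smoothing, object@nfft, length(object@freq),
              min(object@freq), max(object@freq)))
})

setMethod("show", "CueSet", function(object) {
  cat(sprintf("CueSet: %d azimuths x %d frequencies; ITD range [%.3f, %.3f] ms\n",
              length(object@azimuths), length(object@freq),
              min(object@itdMs), max(object@itdMs)))
})
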