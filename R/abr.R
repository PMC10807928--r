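## Design a 2nd-order Butterworth band-pass for the given rate.
designBandpass <- function(fs, lo, hi, order) {
  if (lo <= 0 || lo >= hi) stop("need 0 < lo < hi")
  if (hi >= fs / 2) stop("upper band edge must be below the Nyquist frequency")
  signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
}

## Filter one numeric series; zero-phase (forward-backward) by default.
filterSeries <- function(x, filt, zeroPhase = TRUE) {
  x <- x - mean(x)
  if (zeroPhase) signal::filtfilt(filt, x) else signal::filter(filt, x)
}

#' Band-pass filter ABR data
#'
#' Applies a second-order Butterworth band-pass (default 50-3000 Hz). The
#' default zero-phase (forward-backward) application squares the magnitude
#' response and leaves peak latencies unbiased; `zeroPhase = FALSE` gives the
#' causal single-pass filter. The series mean (DC) is removed before
#' filtering.
#'
#' @param x an [EpochSet-class], [AveragedTrace-class] or numeric vector.
#' @param lo,hi band edges in Hz.
#' @param order filter order (of the underlying low/high-pass prototype).
#' @param zeroPhase logical; apply forward-backward filtering (default TRUE).
#' @param fs sampling rate in Hz (numeric method only).
#' @return an object of the same class as `x`.
#' @export
setGeneric("bandpassFilter",
  function(x, lo = 50, hi = 3000, order = 2, zeroPhase = TRUE, fs = NULL)
    standardGeneric("bandpassFilter"))

#' @rdname bandpassFilter
#' @export
setMethod("bandpassFilter", "EpochSet",
  function(x, lo, hi, order, zeroPhase, fs) {
    filt <- designBandpass(x@fs, lo, hi, order)
    out <- t(apply(x@samples, 1, filterSeries, filt = filt,
                   zeroPhase = zeroPhase))
    initialize(x, samples = out)
  })

#' @rdname bandpassFilter
#' @export
setMethod("bandpassFilter", "AveragedTrace",
  function(x, lo, hi, order, zeroPhase, fs) {
    filt <- designBandpass(x@fs, lo, hi, order)
    v <- filterSeries(x@values, filt, zeroPhase)
    initialize(x, values = v - mean(v))
  })

#' @rdname bandpassFilter
#' @export
setMethod("bandpassFilter", "numeric",
  function(x, lo, hi, order, zeroPhase, fs) {
    if (is.null(fs)) stop("fs is required when filtering a bare numeric series")
    filterSeries(x, designBandpass(fs, lo, hi, order), zeroPhase)
  })

#' Average epochs into a baseline-normalized trace
#'
#' Pointwise mean across epochs, then the full-trace mean is subtracted
#' (baseline normalization) and recorded as `baselineOffset`.
#'
#' @param epochs an [EpochSet-class] with at least one epoch.
#' @return an [AveragedTrace-class].
#' @export
averageEpochs <- function(epochs) {
  stopifnot(is(epochs, "EpochSet"))
  if (nrow(epochs@samples) < 1L) stop("cannot average an empty epoch set")
  m <- colMeans(epochs@samples)
  off <- mean(m)
  new("AveragedTrace", values = m - off, fs = epochs@fs,
      condition = epochs@condition, baselineOffset = off)
}

#' Default per-wave search windows
#'
#' Windows centred on the group mean latencies for the chosen sex, extended
#' `halfWidth` ms to each side and clipped at the midpoints between adjacent
#' wave centres so that windows never overlap.
#'
#' @param sex `"female"` or `"male"`; selects the latency centres.
#' @param halfWidth half-width in ms (default 0.6).
#' @param centers optional explicit wave latency centres in ms (overrides
#'   `sex`).
#' @return data.frame with columns `wave`, `lo`, `hi` (ms).
#' @export
defaultWaveWindows <- function(sex = c("female", "male"), halfWidth = 0.6,
                               centers = NULL) {
  if (is.null(centers)) {
    sex <- match.arg(sex)
    centers <- voleWaveParams(sex)$latMean
  }
  k <- length(centers)
  lo <- centers - halfWidth
  hi <- centers + halfWidth
  if (k > 1) {
    mid <- (centers[-k] + centers[-1]) / 2
    lo[-1] <- pmax(lo[-1], mid)
    hi[-k] <- pmin(hi[-k], mid)
  }
  data.frame(wave = c("I", "II", "III", "IV")[seq_len(k)], lo = lo, hi = hi)
}

## Indices of local maxima of v restricted to window idx (ties -> earlier).
localMaxima <- function(v, idx) {
  n <- length(v)
  idx <- idx[idx > 1 & idx < n]
  idx[v[idx] > v[idx - 1] & v[idx] >= v[idx + 1]]
}

#' Detect and quantify ABR waves I-IV
#'
#' For each wave, the largest local maximum inside its search window is taken
#' as the peak; the trough is the minimum value between that peak and the
#' next wave's peak (the end of the trace for the last wave). Amplitude is
#' peak minus trough and latency is the time of the peak. A wave is flagged
#' absent when its window holds no local maximum or when the resulting
#' amplitude falls below `minProminence`.
#'
#' @param trace an [AveragedTrace-class].
#' @param windows data.frame with columns `wave`, `lo`, `hi` in ms; defaults
#'   to [defaultWaveWindows()]. Windows must be ordered and non-overlapping.
#' @param minProminence minimum peak-to-trough amplitude in uV for a wave to
#'   count as present; defaults to twice the RMS of the final 2 ms of the
#'   trace (assumed post-response).
#' @param animalId,ear provenance tags.
#' @return a [PeakSet-class].
#' @export
detectPeaks <- function(trace, windows = defaultWaveWindows(),
                        minProminence = NULL, animalId = "", ear = "") {
  stopifnot(is(trace, "AveragedTrace"))
  if (nrow(windows) > 1) {
    if (is.unsorted(windows$lo) || any(windows$hi[-nrow(windows)] >
                                       windows$lo[-1] + 1e-9))
      stop("windows must be ordered and non-overlapping")
  }
  v <- trace@values
  t <- (seq_along(v) - 1) / trace@fs * 1000
  if (is.null(minProminence)) {
    tail <- v[t >= max(t) - 2]
    minProminence <- 2 * sqrt(mean(tail^2))
  }
  nw <- nrow(windows)
  peakIdx <- rep(NA_integer_, nw)
  for (w in seq_len(nw)) {
    idx <- which(t >= windows$lo[w] & t <= windows$hi[w])
    cand <- localMaxima(v, idx)
    if (length(cand)) {
      best <- cand[which.max(v[cand])]  # which.max keeps the earliest tie
      peakIdx[w] <- best
    }
  }
  peaks <- data.frame(wave = windows$wave, present = FALSE,
                      peakTime = NA_real_, peakValue = NA_real_,
                      troughValue = NA_real_, amplitude = NA_real_,
                      latency = NA_real_, nEars = 1L,
                      stringsAsFactors = FALSE)
  for (w in seq_len(nw)) {
    if (is.na(peakIdx[w])) next
    nxt <- peakIdx[seq_len(nw) > w & !is.na(peakIdx)]
    endIdx <- if (length(nxt)) nxt[1] else length(v)
    trough <- min(v[peakIdx[w]:endIdx])
    amp <- v[peakIdx[w]] - trough
    if (amp < minProminence) next
    peaks$present[w] <- TRUE
    peaks$peakTime[w] <- t[peakIdx[w]]
    peaks$peakValue[w] <- v[peakIdx[w]]
    peaks$troughValue[w] <- trough
    peaks$amplitude[w] <- amp
    peaks$latency[w] <- t[peakIdx[w]]
  }
  new("PeakSet", peaks = peaks, animalId = animalId, ear = ear)
}

#' Construct an annotation set
#'
#' @param wave character, wave labels (subset of I..IV).
#' @param action character, `"keep"`, `"move"` or `"deselect"` per wave.
#' @param index integer, 1-based sample index for `"move"` actions (NA
#'   otherwise).
#' @return an [AnnotationSet-class].
#' @export
annotationSet <- function(wave, action, index = NA_integer_) {
  new("AnnotationSet",
      actions = data.frame(wave = wave, action = action,
                           index = as.integer(index),
                           stringsAsFactors = FALSE))
}

#' Apply manual annotations to a detected peak set
#'
#' `deselect` marks a wave absent (not quantified); `move` re-quantifies
#' amplitude and latency at the given sample index, with the trough taken
#' between the new peak position and the next present wave's peak (trace end
#' for the last wave); `keep` leaves the automatic pick unchanged.
#'
#' @param peaks a [PeakSet-class].
#' @param ann an [AnnotationSet-class].
#' @param trace the [AveragedTrace-class] the peaks were detected on.
#' @return a [PeakSet-class].
#' @export
applyAnnotations <- function(peaks, ann, trace) {
  stopifnot(is(peaks, "PeakSet"), is(ann, "AnnotationSet"),
            is(trace, "AveragedTrace"))
  v <- trace@values
  t <- (seq_along(v) - 1) / trace@fs * 1000
  p <- peaks@peaks
  for (r in seq_len(nrow(ann@actions))) {
    w <- ann@actions$wave[r]
    i <- match(w, p$wave)
    if (is.na(i)) stop("unknown wave label: ", w)
    act <- ann@actions$action[r]
    if (act == "keep") next
    if (act == "deselect") {
      p$present[i] <- FALSE
      p[i, c("peakTime", "peakValue", "troughValue", "amplitude",
             "latency")] <- NA_real_
    } else {  # move
      idx <- ann@actions$index[r]
      if (is.na(idx) || idx < 1 || idx > length(v))
        stop("move index for wave ", w, " is outside the trace")
      p$present[i] <- TRUE
      p$peakTime[i] <- t[idx]
      p$peakValue[i] <- v[idx]
      later <- p$latency[seq_len(nrow(p)) > i & p$present]
      laterIdx <- if (length(later) && all(is.finite(later)))
        round(min(later) * trace@fs / 1000) + 1 else length(v)
      laterIdx <- min(max(laterIdx, idx), length(v))
      p$troughValue[i] <- min(v[idx:laterIdx])
      p$amplitude[i] <- p$peakValue[i] - p$troughValue[i]
      p$latency[i] <- t[idx]
    }
  }
  new("PeakSet", peaks = p, animalId = peaks@animalId, ear = peaks@ear)
}

#' Average peak quantifications across the two ears
#'
#' Per wave: where both ears have the wave, amplitude and latency are the
#' arithmetic means over ears (`nEars = 2`); where only one ear has it, its
#' values are carried with `nEars = 1`; where neither does, the wave is
#' absent.
#'
#' @param left,right [PeakSet-class] objects over the same wave set.
#' @return a [PeakSet-class] with `ear = "both"`.
#' @export
averageEars <- function(left, right) {
  stopifnot(is(left, "PeakSet"), is(right, "PeakSet"))
  pl <- left@peaks
  pr <- right@peaks
  if (!identical(pl$wave, pr$wave)) stop("ears must share one wave set")
  out <- pl
  for (i in seq_len(nrow(pl))) {
    if (pl$present[i] && pr$present[i]) {
      for (col in c("peakTime", "peakValue", "troughValue", "amplitude",
                    "latency"))
        out[[col]][i] <- (pl[[col]][i] + pr[[col]][i]) / 2
      out$nEars[i] <- 2L
    } else if (pr$present[i]) {
      out[i, ] <- pr[i, ]
      out$nEars[i] <- 1L
    } else if (pl$present[i]) {
      out$nEars[i] <- 1L
    } else {
      out$present[i] <- FALSE
    }
  }
  new("PeakSet", peaks = out, animalId = left@animalId, ear = "both")
}
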