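## Linear convolution via FFT; returns length(a) + length(b) - 1 samples.
fftConv <- function(a, b) {
  n <- length(a) + length(b) - 1L
  N <- 2^ceiling(log2(n))
  A <- stats::fft(c(a, numeric(N - length(a))))
  B <- stats::fft(c(b, numeric(N - length(b))))
  Re(stats::fft(A * B, inverse = TRUE) / N)[seq_len(n)]
}

## Farina inverse filter of a log sweep: time-reversed sweep with exp(-t/L)
## amplitude compensation (-6 dB/octave, so the deconvolved spectrum is flat).
sweepInverseFilter <- function(spec) {
  x <- sweepSignal(spec)
  T <- sweepDuration(spec)
  L <- T / log(spec@fEnd / spec@fStart)
  t <- (seq_len(spec@nPoints) - 1) / spec@fs
  rev(x) * exp(-t / L)
}

## In-band spectral gain of the self-deconvolution x * inv; used to normalize
## so the deconvolved transfer function is unity in the swept band. Cached
## per sweep specification.
.deconvNormCache <- new.env(parent = emptyenv())

deconvNorm <- function(spec) {
  key <- sprintf("%g_%g_%g_%d_%g", spec@fStart, spec@fEnd, spec@fs,
                 spec@nPoints, spec@levelDbfs)
  hit <- .deconvNormCache[[key]]
  if (!is.null(hit)) return(hit)
  x <- sweepSignal(spec)
  d <- fftConv(x, sweepInverseFilter(spec))
  nfft <- 8192L
  peak <- which.max(abs(d))
  i1 <- max(1L, peak - nfft %/% 2L)
  seg <- d[i1:min(length(d), i1 + nfft - 1L)]
  seg <- c(seg, numeric(nfft - length(seg)))
  f <- (0:(nfft - 1)) * spec@fs / nfft
  inband <- f > 2 * spec@fStart & f < 0.9 * spec@fEnd
  g <- stats::median(Mod(stats::fft(seg))[inband])
  if (!is.finite(g) || g <= 0) stop("degenerate sweep specification")
  .deconvNormCache[[key]] <- g
  g
}

#' Deconvolve a swept-sine recording into an impulse response
#'
#' Convolves the recording with the amplitude-compensated time-reversed sweep
#' (the log-sweep inverse filter), normalized so that the deconvolved
#' transfer function of the sweep itself is unity (0 dB) across the swept
#' band. Index 1 of the result is lag zero; a system delay of d samples
#' appears as a peak at index d + 1.
#'
#' @param recording numeric, the recorded response to the sweep, at the
#'   sweep's sampling rate.
#' @param spec the generating [SweepSpec-class].
#' @return an [ImpulseResponse-class] of `length(recording)` samples
#'   (lags 0 .. length-1).
#' @export
deconvolveSweep <- function(recording, spec) {
  validObject(spec)
  if (!is.numeric(recording) || !length(recording))
    stop("recording must be a non-empty numeric vector")
  inv <- sweepInverseFilter(spec)
  M <- length(inv)
  full <- fftConv(recording, inv) / deconvNorm(spec)
  vals <- full[M:length(full)]       # lags 0 .. length(recording) - 1
  new("ImpulseResponse", values = vals, fs = spec@fs)
}

#' Gain spectrum of an impulse response
#'
#' Windows `nfft` samples starting 1 ms before the impulse-response peak
#' (clamped to the trace) and returns the FFT magnitude in dB on the
#' one-sided frequency grid.
#'
#' @param ir an [ImpulseResponse-class].
#' @param nfft FFT length (default 512).
#' @param prePeakMs window start before the peak, ms (default 1).
#' @return a [GainSpectrum-class] with `nfft/2 + 1` points.
#' @export
irSpectrum <- function(ir, nfft = 512L, prePeakMs = 1) {
  stopifnot(is(ir, "ImpulseResponse"))
  v <- ir@values
  peak <- which.max(abs(v))
  start <- max(1L, peak - as.integer(round(prePeakMs * ir@fs / 1000)))
  seg <- v[start:min(length(v), start + nfft - 1L)]
  seg <- c(seg, numeric(nfft - length(seg)))
  S <- stats::fft(seg)[seq_len(nfft / 2 + 1)]
  freq <- (0:(nfft / 2)) * ir@fs / nfft
  new("GainSpectrum", freq = freq, gainDb = 20 * log10(pmax(Mod(S), 1e-12)),
      smoothing = "raw", nfft = as.integer(nfft))
}

#' HRTF gain: animal spectrum re calibration spectrum
#'
#' @param animal,calibration [GainSpectrum-class] objects on the same
#'   frequency grid.
#' @return a [GainSpectrum-class], `animal - calibration` in dB.
#' @export
computeGain <- function(animal, calibration) {
  stopifnot(is(animal, "GainSpectrum"), is(calibration, "GainSpectrum"))
  if (length(animal@freq) != length(calibration@freq) ||
      max(abs(animal@freq - calibration@freq)) > 1e-6)
    stop("frequency grids must match")
  initialize(animal, gainDb = animal@gainDb - calibration@gainDb)
}

#' Fractional-octave smoothing of a gain spectrum
#'
#' Power-domain smoothing with a Gaussian kernel in log2 frequency of SD
#' `fraction / 2` octaves. Kernel weights are normalized at each target
#' frequency, so flat spectra pass unchanged. The zero-frequency bin is
#' copied through.
#'
#' @param spectrum a [GainSpectrum-class].
#' @param fraction octave fraction (default 1/48).
#' @return a [GainSpectrum-class] tagged with the smoothing width.
#' @export
octaveSmooth <- function(spectrum, fraction = 1 / 48) {
  stopifnot(is(spectrum, "GainSpectrum"))
  if (fraction <= 0) stop("fraction must be positive")
  sigma <- fraction / 2
  pos <- which(spectrum@freq > 0)
  lf <- log2(spectrum@freq[pos])
  p <- 10^(spectrum@gainDb[pos] / 10)
  out <- p
  reach <- 6 * sigma
  for (i in seq_along(lf)) {
    j1 <- findInterval(lf[i] - reach, lf) + 1L
    j2 <- findInterval(lf[i] + reach, lf)
    jj <- j1:j2
    w <- exp(-(lf[jj] - lf[i])^2 / (2 * sigma^2))
    out[i] <- sum(w * p[jj]) / sum(w)
  }
  g <- spectrum@gainDb
  g[pos] <- 10 * log10(pmax(out, 1e-24))
  initialize(spectrum, gainDb = g,
             smoothing = sprintf("1/%d octave", round(1 / fraction)))
}

#' Directional transfer functions from per-position gains
#'
#' Subtracts, per frequency, the mean gain across all measured positions, so
#' the DTFs isolate direction-specific spectral features and average to 0 dB
#' at every frequency.
#'
#' @param gains list of [GainSpectrum-class] objects (one per position, same
#'   grid, at least two positions).
#' @return list of [GainSpectrum-class] objects, parallel to `gains`.
#' @export
computeDtf <- function(gains) {
  if (length(gains) < 2L) stop("DTFs require at least two positions")
  f0 <- gains[[1]]@freq
  for (g in gains)
    if (length(g@freq) != length(f0) || max(abs(g@freq - f0)) > 1e-6)
      stop("frequency grids must match")
  mat <- vapply(gains, function(g) g@gainDb, numeric(length(f0)))
  m <- rowMeans(mat)
  lapply(gains, function(g) initialize(g, gainDb = g@gainDb - m))
}

#' Interaural level difference spectrum
#'
#' @param right,left [GainSpectrum-class] objects on the same grid.
#' @return a [GainSpectrum-class], right minus left in dB (positive = right
#'   ear louder).
#' @export
computeIld <- function(right, left) {
  computeGain(right, left)
}

#' Interaural time difference by cross-correlation of impulse responses
#'
#' The ITD is the lag maximizing the cross-correlation of the left- and
#' right-ear impulse responses, relative to the (zero) lag of the
#' autocorrelation peak, with optional parabolic sub-sample interpolation
#' around the peak. Positive ITD means the right ear leads. For speed the
#' responses are cross-correlated in a window around the joint energy peak;
#' this does not move the correlation maximum for direct-path responses.
#'
#' @param leftIr,rightIr [ImpulseResponse-class] objects at one rate/length.
#' @param maxLagMs lag search range, ms (default 2).
#' @param interpolate logical, parabolic peak interpolation (default TRUE).
#' @param trim logical; restrict the cross-correlation to a window around the
#'   joint energy peak (default TRUE). Use FALSE to correlate the full
#'   responses.
#' @return numeric, ITD in ms.
#' @export
estimateItd <- function(leftIr, rightIr, maxLagMs = 2, interpolate = TRUE,
                        trim = TRUE) {
  stopifnot(is(leftIr, "ImpulseResponse"), is(rightIr, "ImpulseResponse"))
  if (abs(leftIr@fs - rightIr@fs) > 1e-9)
    stop("impulse responses must share one sampling rate")
  L <- leftIr@values
  R <- rightIr@values
  if (length(L) != length(R)) stop("impulse responses must share one length")
  if (all(L == 0) || all(R == 0)) stop("all-zero impulse response")
  fs <- leftIr@fs
  K <- as.integer(round(maxLagMs * fs / 1000))
  if (trim) {
    # restrict to the neighbourhood of the joint energy peak
    e <- abs(L) + abs(R)
    peak <- which.max(e)
    win <- as.integer(round(5 * fs / 1000)) + K
    i1 <- max(1L, peak - win)
    i2 <- min(length(L), peak + win)
    L <- L[i1:i2]
    R <- R[i1:i2]
  }
  n <- length(L)
  if (K >= n) K <- n - 1L
  lags <- (-K):K
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(L[(1 + k):n] * R[1:(n - k)])
    else sum(L[1:(n + k)] * R[(1 - k):n])
  }, numeric(1))
  i <- which.max(cc)
  lag <- lags[i]
  if (interpolate && i > 1 && i < length(cc)) {
    denom <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    if (abs(denom) > .Machine$double.eps)
      lag <- lag + 0.5 * (cc[i - 1] - cc[i + 1]) / denom
  }
  lag / fs * 1000
}

#' Predicted maximal ITD from head morphometry
#'
#' The acoustic path across the head is taken as pinna width plus inter-pinna
#' distance; the maximal interaural delay is that length divided by the speed
#' of sound.
#'
#' @param pinnaWidthMm,interPinnaMm mm; alternatively pass a
#'   [HeadModel-class] as the first argument.
#' @param soundSpeed m/s (default 343).
#' @return numeric, maximal ITD in microseconds.
#' @export
predictMaxItd <- function(pinnaWidthMm, interPinnaMm = NULL,
                          soundSpeed = 343) {
  if (is(pinnaWidthMm, "HeadModel")) {
    head <- pinnaWidthMm
    return(predictMaxItd(head@pinnaWidth, head@interPinna, head@soundSpeed))
  }
  if (soundSpeed <= 0) stop("sound speed must be positive")
  if (any(c(pinnaWidthMm, interPinnaMm) < 0))
    stop("head dimensions must be non-negative")
  (pinnaWidthMm + interPinnaMm) / 1000 / soundSpeed * 1e6
}

#' Acoustic path length for a given ITD
#'
#' Companion inverse of [predictMaxItd()]: the head path length whose
#' traversal at the speed of sound takes the given interaural delay.
#'
#' @param itdUs ITD in microseconds.
#' @param soundSpeed m/s (default 343).
#' @return numeric, path length in mm.
#' @export
pathLengthForItd <- function(itdUs, soundSpeed = 343) {
  if (soundSpeed <= 0) stop("sound speed must be positive")
  itdUs * 1e-6 * soundSpeed * 1000
}

#' Effective pinna diameter
#'
#' The diameter of the circle with the same area as an elliptical pinna of
#' the given length and width: `sqrt(length * width)` (the geometric mean).
#'
#' @param lengthMm,widthMm pinna length and width, mm.
#' @return numeric, mm.
#' @examples
#' effectiveDiameter(13.0, 10.2)  # 11.5 to table precision
#' @export
effectiveDiameter <- function(lengthMm, widthMm) {
  if (any(lengthMm <= 0) || any(widthMm <= 0))
    stop("pinna dimensions must be positive")
  sqrt(lengthMm * widthMm)
}

#' Full binaural cue extraction from a measurement scene
#'
#' Runs the complete pipeline on a two-ear sweep scene: sweep deconvolution
#' per ear and for the calibration recording, 512-point gain spectra,
#' calibration subtraction, fractional-octave smoothing, DTF computation per
#' ear, ILD spectra (right - left), and cross-correlation ITDs per azimuth.
#'
#' @param scene an [HRTFScene-class].
#' @param nfft FFT length for the gain spectra (default 512).
#' @param smoothFraction octave fraction for smoothing (default 1/48);
#'   `NULL` skips smoothing.
#' @param maxLagMs ITD search range, ms.
#' @return a [CueSet-class].
#' @export
hrtfCues <- function(scene, nfft = 512L, smoothFraction = 1 / 48,
                     maxLagMs = 2) {
  stopifnot(is(scene, "HRTFScene"))
  calIr <- deconvolveSweep(scene@calibration, scene@sweep)
  calSpec <- irSpectrum(calIr, nfft = nfft)
  naz <- length(scene@azimuths)
  gainL <- gainR <- vector("list", naz)
  itd <- numeric(naz)
  for (k in seq_len(naz)) {
    irL <- deconvolveSweep(scene@left[[k]], scene@sweep)
    irR <- deconvolveSweep(scene@right[[k]], scene@sweep)
    gL <- computeGain(irSpectrum(irL, nfft = nfft), calSpec)
    gR <- computeGain(irSpectrum(irR, nfft = nfft), calSpec)
    if (!is.null(smoothFraction)) {
      gL <- octaveSmooth(gL, smoothFraction)
      gR <- octaveSmooth(gR, smoothFraction)
    }
    gainL[[k]] <- gL
    gainR[[k]] <- gR
    itd[k] <- estimateItd(irL, irR, maxLagMs = maxLagMs)
  }
  dtfL <- computeDtf(gainL)
  dtfR <- computeDtf(gainR)
  freq <- gainL[[1]]@freq
  asMat <- function(lst) vapply(lst, function(g) g@gainDb,
                                numeric(length(freq)))
  gl <- asMat(gainL)
  gr <- asMat(gainR)
  new("CueSet", azimuths = scene@azimuths, freq = freq,
      gainLeft = gl, gainRight = gr,
      dtfLeft = asMat(dtfL), dtfRight = asMat(dtfR),
      ild = gr - gl, itdMs = itd)
}
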