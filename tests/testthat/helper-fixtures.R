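# Small fixture builders shared across test files.

# A light generator configuration for fast tests.
quickConfig <- function(sex = "female", nEpochs = 50L, noiseSd = 1,
                        seed = 1L, ...) {
  abrSimConfig(sex, nEpochs = nEpochs, noiseSd = noiseSd, seed = seed, ...)
}

# Build a baseline-normalized AveragedTrace from raw values.
makeTrace <- function(values, fs = 97656.25,
                      condition = stimulusCondition()) {
  new("AveragedTrace", values = values - mean(values), fs = fs,
      condition = condition, baselineOffset = mean(values))
}

# Time axis (ms) for n samples at fs.
timeAxis <- function(n, fs) (seq_len(n) - 1) / fs * 1000

# A trace of Gaussian bumps: amps (uV) at lats (ms), SD widths (ms).
gaussTrace <- function(amps, lats, widths, fs = 97656.25, durMs = 12) {
  t <- timeAxis(round(durMs * fs / 1000), fs)
  v <- numeric(length(t))
  for (i in seq_along(amps))
    v <- v + amps[i] * exp(-(t - lats[i])^2 / (2 * widths[i]^2))
  makeTrace(v, fs)
}

# Exhaustive-scan oracle for peak quantification: for each window, scan every
# interior sample for local maxima (ties to the earlier index), take the
# largest, then the minimum between that peak and the next wave's peak (trace
# end for the last wave). Independent of the package implementation.
oraclePeaks <- function(v, t, windows) {
  nw <- nrow(windows)
  peakIdx <- rep(NA_integer_, nw)
  for (w in seq_len(nw)) {
    best <- NA_integer_
    for (i in 2:(length(v) - 1)) {
      if (t[i] < windows$lo[w] || t[i] > windows$hi[w]) next
      if (v[i] > v[i - 1] && v[i] >= v[i + 1]) {
        if (is.na(best) || v[i] > v[best]) best <- i
      }
    }
    peakIdx[w] <- best
  }
  out <- data.frame(peakIdx = peakIdx, trough = NA_real_, amp = NA_real_)
  for (w in seq_len(nw)) {
    if (is.na(peakIdx[w])) next
    later <- peakIdx[seq_len(nw) > w]
    later <- later[!is.na(later)]
    end <- if (length(later)) later[1] else length(v)
    out$trough[w] <- min(v[peakIdx[w]:end])
    out$amp[w] <- v[peakIdx[w]] - out$trough[w]
  }
  out
}

# Exhaustive lag-search oracle for the cross-correlation ITD (integer lags).
oracleItdLag <- function(L, R, K) {
  n <- length(L)
  best <- -Inf
  bestLag <- 0L
  for (k in (-K):K) {
    s <- 0
    for (ti in 1:n) {
      tj <- ti - k
      if (tj >= 1 && tj <= n) s <- s + L[ti] * R[tj]
    }
    if (s > best) {
      best <- s
      bestLag <- k
    }
  }
  bestLag
}
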