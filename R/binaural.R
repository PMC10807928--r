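#' Compute the binaural interaction component (BIC)
#'
#' `BIC(t) = binaural(t) - [left(t) + right(t)]`, pointwise over three
#' baseline-normalized averaged traces of equal length and rate. The monaural
#' traces are not time-shifted before summation. With this sign convention
#' the first binaural interaction deflection (DN1) is negative; amplitudes
#' are reported as magnitudes downstream.
#'
#' @param left,right,binaural [AveragedTrace-class] objects.
#' @param itd the interaural time difference of the binaural condition, ms;
#'   defaults to the binaural trace's condition ITD when available.
#' @return a [BICTrace-class].
#' @export
computeBic <- function(left, right, binaural, itd = NULL) {
  stopifnot(is(left, "AveragedTrace"), is(right, "AveragedTrace"),
            is(binaural, "AveragedTrace"))
  n <- length(binaural@values)
  if (length(left@values) != n || length(right@values) != n)
    stop("traces must have equal length")
  if (abs(left@fs - binaural@fs) > 1e-9 || abs(right@fs - binaural@fs) > 1e-9)
    stop("traces must share one sampling rate")
  if (is.null(itd)) itd <- binaural@condition@itd
  if (is.null(itd) || is.na(itd)) itd <- NA_real_
  new("BICTrace", values = binaural@values - (left@values + right@values),
      fs = binaural@fs, itd = itd,
      provenance = c(left = left@condition@ear, right = right@condition@ear,
                     binaural = binaural@condition@ear))
}

#' Measure the DN1 deflection of a BIC trace
#'
#' DN1 is the most negative local extremum of the BIC inside the search
#' window; its magnitude relative to the zero baseline is the DN1 amplitude
#' and its time the DN1 latency. The deflection counts as present when its
#' magnitude reaches `criterion`; by default twice the RMS of the BIC trace
#' outside the window (the noise estimate).
#'
#' @param bic a [BICTrace-class].
#' @param window numeric length 2, search window in ms (default 3.5-8 ms,
#'   bracketing wave IV and the observed DN1 latency range).
#' @param criterion minimum deflection magnitude in uV; `NULL` for the
#'   2 x out-of-window RMS default.
#' @return a [BICMeasure-class].
#' @export
measureDn1 <- function(bic, window = c(3.5, 8), criterion = NULL) {
  stopifnot(is(bic, "BICTrace"))
  v <- bic@values
  t <- (seq_along(v) - 1) / bic@fs * 1000
  idx <- which(t >= window[1] & t <= window[2])
  if (!length(idx)) stop("search window lies outside the trace")
  if (is.null(criterion)) {
    out <- v[-idx]
    criterion <- if (length(out)) 2 * sqrt(mean(out^2)) else 0
  }
  n <- length(v)
  cand <- idx[idx > 1 & idx < n]
  cand <- cand[v[cand] < v[cand - 1] & v[cand] <= v[cand + 1]]
  if (!length(cand))
    return(new("BICMeasure", amplitude = NA_real_, latency = NA_real_,
               itd = bic@itd, present = FALSE))
  best <- cand[which.min(v[cand])]
  val <- v[best]
  present <- is.finite(val) && val < 0 && abs(val) >= criterion
  new("BICMeasure",
      amplitude = if (present) abs(val) else NA_real_,
      latency = if (present) t[best] else NA_real_,
      itd = bic@itd, present = present)
}

#' DN1 amplitude and latency across the ITD grid
#'
#' Runs [computeBic()] then [measureDn1()] at every ITD of a binaural
#' session. Session elements may hold [EpochSet-class] objects (averaged and
#' baseline-normalized here) or ready [AveragedTrace-class] objects. An ITD
#' whose left, right or binaural member is missing yields an absent point.
#'
#' @param sessions named list itd -> list(left, right, binaural), as returned
#'   by [generateBinauralSession()].
#' @param window,criterion passed to [measureDn1()].
#' @param filter logical; band-pass filter the averaged traces (50-3000 Hz)
#'   before computing the BIC (default TRUE).
#' @return a [BICCurve-class], ordered by ITD.
#' @export
bicCurve <- function(sessions, window = c(3.5, 8), criterion = NULL,
                     filter = TRUE) {
  itds <- as.numeric(names(sessions))
  if (any(is.na(itds))) stop("session names must be ITDs in ms")
  ord <- order(itds)
  rows <- lapply(ord, function(k) {
    s <- sessions[[k]]
    itd <- itds[k]
    if (is.null(s$left) || is.null(s$right) || is.null(s$binaural))
      return(data.frame(itd = itd, amplitude = NA_real_,
                        latency = NA_real_, present = FALSE))
    asTrace <- function(x) {
      tr <- if (is(x, "EpochSet")) averageEpochs(x) else x
      if (filter) bandpassFilter(tr) else tr
    }
    bic <- computeBic(asTrace(s$left), asTrace(s$right), asTrace(s$binaural),
                      itd = itd)
    m <- measureDn1(bic, window = window, criterion = criterion)
    data.frame(itd = itd, amplitude = m@amplitude, latency = m@latency,
               present = m@present)
  })
  new("BICCurve", measures = do.call(rbind, rows))
}
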