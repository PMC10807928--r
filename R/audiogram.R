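#' Construct a level series
#'
#' @param levels numeric, dB SPL, strictly descending in exact 10 dB steps.
#' @param traces list of [AveragedTrace-class], parallel to `levels`.
#' @param label frequency tag (kHz as character) or `"click"`.
#' @return a [LevelSeries-class].
#' @export
levelSeries <- function(levels, traces, label = "click") {
  new("LevelSeries", levels = levels, traces = traces, label = label)
}

#' Automated response-presence decision
#'
#' Surrogate for the trained human observer: the score is the peak-to-peak
#' voltage of the trace inside the response window divided by a peak-to-peak
#' noise estimate, and the response counts as present when the score reaches
#' `criterion`. The noise estimate comes from a separate noise reference
#' trace (same window) when given, otherwise from the trace's own noise
#' window (default: the final 2 ms of a 12 ms epoch, assumed post-response).
#'
#' The score is a ratio, so it is invariant to scaling trace and noise
#' reference by a common constant.
#'
#' @param trace an [AveragedTrace-class].
#' @param noiseRef optional [AveragedTrace-class] used as the noise reference.
#' @param criterion presence criterion on the score (default 2).
#' @param responseWindow numeric length 2, ms (default 1-8 ms, bracketing the
#'   wave latencies).
#' @param noiseWindow numeric length 2, ms; used when `noiseRef` is absent.
#' @return list with elements `present` (logical) and `score` (numeric).
#' @export
responsePresent <- function(trace, noiseRef = NULL, criterion = 2,
                            responseWindow = c(1, 8), noiseWindow = NULL) {
  stopifnot(is(trace, "AveragedTrace"))
  v <- trace@values
  t <- (seq_along(v) - 1) / trace@fs * 1000
  if (is.null(noiseWindow)) noiseWindow <- c(max(t) - 2, max(t))
  inResp <- v[t >= responseWindow[1] & t <= responseWindow[2]]
  if (!length(inResp)) stop("response window lies outside the trace")
  noise <- if (is.null(noiseRef)) {
    v[t >= noiseWindow[1] & t <= noiseWindow[2]]
  } else {
    stopifnot(is(noiseRef, "AveragedTrace"))
    if (abs(noiseRef@fs - trace@fs) > 1e-9)
      stop("noise reference must share the trace's sampling rate")
    nv <- noiseRef@values
    nt <- (seq_along(nv) - 1) / noiseRef@fs * 1000
    nv[nt >= responseWindow[1] & nt <= responseWindow[2]]
  }
  ppNoise <- diff(range(noise))
  if (!is.finite(ppNoise) || ppNoise <= 0)
    stop("degenerate (constant) noise reference")
  score <- diff(range(inResp)) / ppNoise
  list(present = score >= criterion, score = score)
}

#' Midpoint threshold rule over level decisions
#'
#' The descending-step rule: the threshold is the midpoint of the last level
#' that elicited a response and the first lower level that did not (e.g.
#' present at 60 dB SPL and absent at 50 dB SPL gives 55 dB SPL). A response
#' at every tested level is censored `below_min`; no response at any level is
#' censored `above_max`. Non-monotone decisions (a response below an absent
#' level) trigger a warning and the lowest present level above the first
#' absence is used.
#'
#' @param levels numeric, dB SPL, descending.
#' @param present logical, parallel decisions.
#' @return list with `threshold` (dB SPL or NA) and `censored` (`"none"`,
#'   `"below_min"`, `"above_max"`).
#' @export
thresholdFromDecisions <- function(levels, present) {
  stopifnot(length(levels) == length(present))
  ord <- order(levels, decreasing = TRUE)
  levels <- levels[ord]
  present <- present[ord]
  if (all(present)) return(list(threshold = NA_real_, censored = "below_min"))
  if (!any(present)) return(list(threshold = NA_real_, censored = "above_max"))
  firstAbsent <- which(!present)[1]
  if (firstAbsent == 1L)
    return(list(threshold = NA_real_, censored = "above_max"))
  if (any(present[firstAbsent:length(present)]))
    warning("non-monotone level decisions; using the lowest response above ",
            "the first absence")
  lastPresent <- firstAbsent - 1L
  list(threshold = (levels[lastPresent] + levels[firstAbsent]) / 2,
       censored = "none")
}

#' Estimate the ABR threshold of a descending level series
#'
#' Applies [responsePresent()] at every level and the midpoint rule
#' ([thresholdFromDecisions()]) to the resulting decisions.
#'
#' @param series a [LevelSeries-class].
#' @param criterion presence criterion on the score (default 2).
#' @param noiseRef optional noise reference trace passed to
#'   [responsePresent()].
#' @param responseWindow response window in ms.
#' @return a [ThresholdResult-class].
#' @export
estimateThreshold <- function(series, criterion = 2, noiseRef = NULL,
                              responseWindow = c(1, 8)) {
  stopifnot(is(series, "LevelSeries"))
  dec <- lapply(series@traces, responsePresent, noiseRef = noiseRef,
                criterion = criterion, responseWindow = responseWindow)
  decisions <- data.frame(
    level = series@levels,
    present = vapply(dec, `[[`, logical(1), "present"),
    score = vapply(dec, `[[`, numeric(1), "score"))
  r <- thresholdFromDecisions(decisions$level, decisions$present)
  new("ThresholdResult", threshold = r$threshold, censored = r$censored,
      decisions = decisions, label = series@label)
}

#' Assemble an audiogram from per-frequency threshold results
#'
#' @param results named list, names are tone frequencies in kHz (from the
#'   1-46 kHz test set), values are [ThresholdResult-class] objects. Censored
#'   entries are carried through unaltered.
#' @return an [Audiogram-class].
#' @export
buildAudiogram <- function(results) {
  if (!length(results)) stop("results must be non-empty")
  freqs <- as.numeric(names(results))
  if (any(is.na(freqs))) stop("result names must be frequencies in kHz")
  ord <- order(freqs)
  new("Audiogram", frequencies = freqs[ord], results = results[ord])
}

#' Frequency of best sensitivity
#'
#' @param audiogram an [Audiogram-class].
#' @return numeric, the frequency (kHz) with the lowest uncensored threshold
#'   (`NA` when every entry is censored).
#' @export
bestFrequency <- function(audiogram) {
  stopifnot(is(audiogram, "Audiogram"))
  th <- thresholdValue(audiogram)
  if (all(is.na(th))) return(NA_real_)
  audiogram@frequencies[which.min(th)]
}

#' Tidy audiogram table
#'
#' @param audiogram an [Audiogram-class].
#' @param animalId provenance tag.
#' @return data.frame with columns animal, frequency_khz, threshold_db_spl,
#'   censored.
#' @export
audiogramTable <- function(audiogram, animalId = "") {
  data.frame(
    animal = animalId,
    frequency_khz = audiogram@frequencies,
    threshold_db_spl = vapply(audiogram@results, function(r) r@threshold,
                              numeric(1)),
    censored = vapply(audiogram@results, function(r) r@censored,
                      character(1)))
}
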