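#' Group summary: mean, standard error, range, n
#'
#' The reporting convention of the extracted feature tables:
#' mean +/- standard error (range, N), with the sample SD (n - 1
#' denominator) in the SE.
#'
#' @param values numeric, non-empty.
#' @return one-row data.frame with columns `mean`, `se`, `min`, `max`, `n`.
#' @export
summarizeValues <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("values must be non-empty")
  n <- length(values)
  se <- if (n > 1) stats::sd(values) / sqrt(n) else 0
  data.frame(mean = mean(values), se = se, min = min(values),
             max = max(values), n = n)
}

#' Three-SD outlier filter
#'
#' Single-pass rule: values farther than `k` sample SDs from the full-sample
#' mean are removed (mean and SD are computed once on the full input, not
#' re-iterated). A zero-SD sample keeps all values.
#'
#' @param values numeric, length >= 2.
#' @param k SD multiple (default 3).
#' @return list with `kept`, `removed`, `mean`, `sd`.
#' @export
outlierFilter <- function(values, k = 3) {
  if (length(values) < 2L) stop("need at least two values")
  m <- mean(values)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    return(list(kept = values, removed = numeric(0), mean = m, sd = s))
  out <- abs(values - m) > k * s
  list(kept = values[!out], removed = values[out], mean = m, sd = s)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and (by default) a two-tailed p-value.
#'
#' @param a,b numeric groups, each of length >= 2.
#' @param twoTailed logical (default TRUE).
#' @return list with `t`, `df`, `p`.
#' @export
welchT <- function(a, b, twoTailed = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least two values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("degenerate: zero variance in both groups")
  alt <- if (twoTailed) "two.sided" else "less"
  fit <- stats::t.test(a, b, var.equal = FALSE, alternative = alt)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' Collate peak sets into a tidy feature table
#'
#' @param peakSets list of [PeakSet-class] objects.
#' @param sex optional character vector parallel to `peakSets`.
#' @return data.frame with columns animal, sex, ear, wave, amplitude_uV,
#'   latency_ms, present.
#' @export
peakFeatureTable <- function(peakSets, sex = NULL) {
  rows <- lapply(seq_along(peakSets), function(i) {
    p <- peakSets[[i]]@peaks
    data.frame(animal = peakSets[[i]]@animalId,
               sex = if (is.null(sex)) NA_character_ else sex[i],
               ear = peakSets[[i]]@ear,
               wave = p$wave,
               amplitude_uV = p$amplitude,
               latency_ms = p$latency,
               present = p$present)
  })
  do.call(rbind, rows)
}
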