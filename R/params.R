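#' Tone frequencies of the audiogram test set
#'
#' @return numeric, kHz: 1, 2, 4, 8, 16, 24, 32, 46.
#' @export
toneFrequencies <- function() .TONE_FREQS

#' ITD grid for binaural click stimulation
#'
#' @return numeric, ms: -2 to +2 in 0.5 ms steps.
#' @export
itdGrid <- function() .ITD_GRID

#' Prairie vole ABR wave parameters (published group statistics)
#'
#' Per-wave click-ABR peak-to-trough amplitudes and latencies at 90 dB SPL for
#' male and female prairie voles: group mean, standard error and group size.
#' The between-animal SD columns are derived as `SE * sqrt(n)` and drive the
#' per-animal draws of the synthetic generator.
#'
#' @param sex `"female"` or `"male"`.
#' @return data.frame with columns `wave`, `ampMean`, `ampSE`, `latMean`,
#'   `latSE`, `n`, `ampSd`, `latSd` (uV and ms).
#' @export
voleWaveParams <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  tab <- switch(sex,
    female = data.frame(
      wave = c("I", "II", "III", "IV"),
      ampMean = c(4.9, 4.2, 1.8, 3.2),
      ampSE   = c(0.22, 0.20, 0.054, 0.085),
      latMean = c(2.02, 2.98, 3.71, 4.83),
      latSE   = c(0.05, 0.06, 0.09, 0.12),
      n = 9L),
    male = data.frame(
      wave = c("I", "II", "III", "IV"),
      ampMean = c(3.2, 3.1, 2.5, 3.4),
      ampSE   = c(0.10, 0.14, 0.13, 0.13),
      latMean = c(1.96, 2.76, 3.43, 4.43),
      latSE   = c(0.03, 0.05, 0.06, 0.07),
      n = 10L))
  tab$ampSd <- tab$ampSE * sqrt(tab$n)
  tab$latSd <- tab$latSE * sqrt(tab$n)
  tab
}

#' Prairie vole DN1 parameters across ITD (published group statistics)
#'
#' DN1 (first negative deflection of the binaural interaction component)
#' amplitude and latency versus interaural time difference, with group means,
#' standard errors and group size (n = 9 per sex). SD columns are
#' `SE * sqrt(n)`.
#'
#' @param sex `"female"` or `"male"`.
#' @return data.frame with columns `itd` (ms), `ampMean`, `ampSE` (uV),
#'   `latMean`, `latSE` (ms), `n`, `ampSd`, `latSd`.
#' @export
voleBicParams <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  itd <- seq(-2, 2, by = 0.5)
  tab <- switch(sex,
    male = data.frame(
      itd = itd,
      ampMean = c(2.7, 2.6, 3.4, 3.4, 3.0, 3.4, 2.9, 2.6, 2.8),
      ampSE   = c(0.53, 0.44, 0.70, 0.55, 0.55, 0.53, 0.39, 0.49, 0.40),
      latMean = c(6.3, 5.9, 5.3, 4.9, 4.5, 5.0, 5.4, 5.8, 6.3),
      latSE   = c(0.17, 0.08, 0.11, 0.09, 0.09, 0.10, 0.11, 0.14, 0.16),
      n = 9L),
    female = data.frame(
      itd = itd,
      ampMean = c(1.8, 2.1, 3.1, 2.6, 3.1, 2.6, 2.9, 2.4, 2.0),
      ampSE   = c(0.35, 0.43, 0.70, 0.49, 0.56, 0.50, 0.57, 0.44, 0.43),
      latMean = c(6.6, 6.0, 5.6, 5.0, 4.6, 5.2, 5.7, 5.9, 6.3),
      latSE   = c(0.12, 0.08, 0.11, 0.09, 0.09, 0.14, 0.10, 0.22, 0.18),
      n = 9L))
  tab$ampSd <- tab$ampSE * sqrt(tab$n)
  tab$latSd <- tab$latSE * sqrt(tab$n)
  tab
}

#' Prairie vole hearing thresholds (published group statistics)
#'
#' Mean tone-ABR thresholds by frequency plus the click threshold, per sex.
#'
#' @param sex `"female"` or `"male"`.
#' @return data.frame with columns `label` (kHz as character, or "click"),
#'   `mean` (dB SPL), `se`, `n`.
#' @export
voleThresholds <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  switch(sex,
    male = data.frame(
      label = c("1", "2", "4", "8", "16", "24", "32", "46", "click"),
      mean = c(46.2, 37.5, 40.0, 25.0, 28.8, 35.0, 28.8, 38.8, 65.4),
      se = c(7.2, 6.4, 2.7, 2.7, 3.2, 3.8, 4.6, 4.2, 1.99),
      n = c(rep(7L, 8), 12L)),
    female = data.frame(
      label = c("1", "2", "4", "8", "16", "24", "32", "46", "click"),
      mean = c(50.6, 38.3, 40.6, 26.1, 31.7, 37.3, 31.7, 45.0, 63.2),
      se = c(2.9, 3.7, 2.9, 2.0, 3.3, 2.8, 2.4, 2.4, 1.21),
      n = c(rep(9L, 8), 11L)))
}

#' Prairie vole head and pinna morphometry (published group means)
#'
#' @return data.frame with columns `measure`, `male`, `female`, `units`.
#' @export
voleMorphometry <- function() {
  data.frame(
    measure = c("nose_to_pinna", "inter_pinna", "pinna_width",
                "pinna_length", "effective_diameter", "weight"),
    male = c(27.7, 15.3, 10.7, 13.2, 11.8, 39.2),
    female = c(27.4, 15.4, 10.2, 13.0, 11.5, 31.5),
    units = c("mm", "mm", "mm", "mm", "mm", "g"))
}

#' Linear-in-dB amplitude growth with a hard threshold
#'
#' The default level growth model of the synthetic generator: response
#' amplitude scales linearly in dB above the true threshold and saturates at
#' 90 dB SPL; below the threshold the scale is exactly zero.
#'
#' @param level numeric, dB SPL.
#' @param threshold numeric, true threshold in dB SPL.
#' @return numeric scale in [0, 1].
#' @export
linearGrowth <- function(level, threshold) {
  span <- max(90 - threshold, 1e-9)
  ifelse(level <= threshold, 0, pmin(1, (level - threshold) / span))
}
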