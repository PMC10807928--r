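#' Wave parameter recovery study on synthetic click-ABR sessions
#'
#' Simulates a cohort of animals from the group tables for the chosen sex,
#' runs the full monaural analysis pipeline per animal and ear (band-pass
#' filtering of epochs, averaging, peak detection, ear averaging), and
#' returns the per-animal wave quantifications together with across-animal
#' summaries. This is the package's end-to-end validation of the wave
#' quantification stage: the across-animal means should land within sampling
#' error of the generating group means.
#'
#' @param sex `"female"` or `"male"`.
#' @param nAnimals simulated animals (default 9).
#' @param nEpochs epochs per ear and animal (default 500).
#' @param noiseSd epoch noise SD, uV (default 3).
#' @param level click level, dB SPL (default 90).
#' @param seed base RNG seed.
#' @return list with `perAnimal` (data.frame: animal, wave, amplitude_uV,
#'   latency_ms, present) and `summary` (data.frame per wave: mean/SE of
#'   amplitude and latency over animals with the wave present).
#' @export
simulateWaveRecovery <- function(sex = "female", nAnimals = 9L,
                                 nEpochs = 500L, noiseSd = 3, level = 90,
                                 seed = 1L) {
  base <- abrSimConfig(sex, nEpochs = nEpochs, noiseSd = noiseSd, seed = seed)
  animals <- simulateAnimals(base, nAnimals = nAnimals, seed = seed)
  windows <- defaultWaveWindows(sex)
  rows <- lapply(seq_along(animals), function(a) {
    acfg <- animals[[a]]
    quant <- function(ear, s) {
      ep <- generateAbrEpochs(acfg,
                              stimulusCondition(ear, "click", level = level),
                              seed = deriveSeed(acfg@seed, s),
                              animalId = sprintf("animal%02d", a))
      detectPeaks(averageEpochs(bandpassFilter(ep)), windows = windows,
                  animalId = sprintf("animal%02d", a), ear = ear)
    }
    avg <- averageEars(quant("left", 1), quant("right", 2))
    p <- avg@peaks
    data.frame(animal = sprintf("animal%02d", a), wave = p$wave,
               amplitude_uV = p$amplitude, latency_ms = p$latency,
               present = p$present)
  })
  perAnimal <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(perAnimal, perAnimal$wave),
                                function(d) {
    d <- d[d$present, , drop = FALSE]
    sa <- summarizeValues(d$amplitude_uV)
    sl <- summarizeValues(d$latency_ms)
    data.frame(wave = d$wave[1], n = sa$n,
               ampMean = sa$mean, ampSE = sa$se,
               latMean = sl$mean, latSE = sl$se)
  }))
  summ <- summ[match(c("I", "II", "III", "IV"), summ$wave), ]
  rownames(summ) <- NULL
  list(perAnimal = perAnimal, summary = summ)
}

#' DN1 recovery study on synthetic binaural sessions
#'
#' Simulates a cohort of animals, generates the binaural session across the
#' ITD grid for each, computes the binaural interaction component per ITD and
#' measures the DN1 deflection, returning per-animal curves and across-animal
#' summaries.
#'
#' @param sex `"male"` or `"female"`.
#' @param nAnimals simulated animals (default 9).
#' @param itds ITD grid, ms.
#' @param nEpochs epochs per condition (default 500).
#' @param noiseSd epoch noise SD, uV (default 3).
#' @param seed base RNG seed.
#' @return list with `perAnimal` (data.frame: animal, itd, amplitude_uV,
#'   latency_ms, present) and `summary` (per itd: mean/SE of amplitude and
#'   latency over animals with DN1 present).
#' @export
simulateBicRecovery <- function(sex = "male", nAnimals = 9L,
                                itds = itdGrid(), nEpochs = 500L,
                                noiseSd = 3, seed = 1L) {
  base <- abrSimConfig(sex, nEpochs = nEpochs, noiseSd = noiseSd, seed = seed)
  animals <- simulateAnimals(base, nAnimals = nAnimals, seed = seed)
  rows <- lapply(seq_along(animals), function(a) {
    acfg <- animals[[a]]
    ses <- generateBinauralSession(acfg, itds = itds,
                                   seed = deriveSeed(acfg@seed, 3),
                                   animalId = sprintf("animal%02d", a))
    m <- bicTable(bicCurve(ses))
    data.frame(animal = sprintf("animal%02d", a), itd = m$itd,
               amplitude_uV = m$amplitude, latency_ms = m$latency,
               present = m$present)
  })
  perAnimal <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(perAnimal, perAnimal$itd),
                                function(d) {
    d <- d[d$present, , drop = FALSE]
    if (!nrow(d))
      return(data.frame(itd = NA_real_, n = 0L, ampMean = NA_real_,
                        ampSE = NA_real_, latMean = NA_real_,
                        latSE = NA_real_))
    sa <- summarizeValues(d$amplitude_uV)
    sl <- summarizeValues(d$latency_ms)
    data.frame(itd = d$itd[1], n = sa$n, ampMean = sa$mean, ampSE = sa$se,
               latMean = sl$mean, latSE = sl$se)
  }))
  summ <- summ[order(summ$itd), ]
  rownames(summ) <- NULL
  list(perAnimal = perAnimal, summary = summ)
}
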