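#' Construct a stimulus condition
#'
#' @param ear `"left"`, `"right"` or `"binaural"`.
#' @param kind `"click"` or `"tone"`.
#' @param frequency tone frequency in kHz (ignored for clicks).
#' @param level presentation level in dB SPL.
#' @param itd interaural time difference in ms (binaural only).
#' @return a [StimulusCondition-class].
#' @examples
#' stimulusCondition("left", "click", level = 90)
#' stimulusCondition("binaural", "click", level = 90, itd = 0.5)
#' @export
stimulusCondition <- function(ear = "left", kind = "click",
                              frequency = NA_real_, level = 90,
                              itd = NA_real_) {
  new("StimulusCondition", ear = ear, kind = kind,
      frequency = as.numeric(frequency), level = as.numeric(level),
      itd = as.numeric(itd))
}

#' Construct an ABR simulation configuration
#'
#' Builds the generator configuration from published group statistics for the
#' chosen sex. Epochs are 12 ms at 97656.25 Hz by default, with four Gaussian
#' wave templates whose means come from the group tables and whose
#' between-animal SDs are `SE * sqrt(n)`.
#'
#' The template width (0.15 ms SD) is chosen so that the peak-to-trough
#' amplitude of each template wave equals its amplitude parameter to within a
#' few percent after 50-3000 Hz filtering, while adjacent waves remain
#' resolvable; see the package vignette.
#'
#' @param sex `"female"` or `"male"`; selects the wave and DN1 tables.
#' @param nEpochs epochs per condition (default 500).
#' @param noiseSd additive epoch noise SD in uV (default 3).
#' @param epochDur epoch duration in ms (default 12).
#' @param fs sampling rate in Hz (default 97656.25).
#' @param waveWidth Gaussian SD per wave template, ms.
#' @param growth level growth function; see [linearGrowth()].
#' @param trueThreshold generating threshold in dB SPL for level series.
#' @param bicParams DN1 parameter table; defaults to [voleBicParams()] for
#'   `sex`.
#' @param dn1Width Gaussian SD of the injected DN1 deflection, ms.
#' @param waveParams wave parameter table; defaults to [voleWaveParams()] for
#'   `sex`.
#' @param seed base RNG seed.
#' @return an [ABRSimConfig-class].
#' @examples
#' cfg <- abrSimConfig("female", nEpochs = 100)
#' @export
abrSimConfig <- function(sex = c("female", "male"), nEpochs = 500L,
                         noiseSd = 3, epochDur = 12, fs = 97656.25,
                         waveWidth = rep(0.15, 4), growth = linearGrowth,
                         trueThreshold = 55,
                         bicParams = voleBicParams(sex),
                         dn1Width = 0.3,
                         waveParams = voleWaveParams(sex),
                         seed = 1L) {
  sex <- match.arg(sex)
  new("ABRSimConfig", waveParams = waveParams, waveWidth = waveWidth,
      noiseSd = noiseSd, nEpochs = as.integer(nEpochs), epochDur = epochDur,
      fs = fs, growth = growth, trueThreshold = trueThreshold,
      bicParams = bicParams, dn1Width = dn1Width, seed = as.integer(seed))
}

## Time axis of one epoch, ms.
epochTime <- function(config) {
  n <- round(config@epochDur * config@fs / 1000)
  (seq_len(n) - 1) / config@fs * 1000
}

## Peak-to-trough of an isolated unit wave after the standard 50-3000 Hz
## zero-phase analysis filter. Wave amplitudes are specified in the
## measurement convention (band-passed peak-to-trough), so templates divide
## by this factor; see the methods vignette.
waveUnitMeasure <- function(config, lat, width) {
  t <- epochTime(config)
  g <- exp(-(t - lat)^2 / (2 * width^2))
  y <- bandpassFilter(g, fs = config@fs)
  peak <- which.max(y)
  y[peak] - min(y[peak:length(y)])
}

#' Noiseless ABR template of a configuration
#'
#' Sum of per-wave Gaussian deflections at the configured amplitudes and
#' latencies, scaled by the growth function at the condition's level. The
#' amplitude parameters follow the measurement convention -- the
#' peak-to-trough voltage of the band-passed (50-3000 Hz) average -- so each
#' wave's template is pre-compensated for the passband attenuation of an
#' isolated wave of its width.
#'
#' @param config an [ABRSimConfig-class].
#' @param condition a [StimulusCondition-class] (its level sets the growth
#'   scale via `config@growth` and `config@trueThreshold`).
#' @return numeric, the template trace (uV) on the epoch time grid.
#' @export
abrTemplate <- function(config, condition = stimulusCondition()) {
  t <- epochTime(config)
  scale <- config@growth(condition@level, config@trueThreshold)
  wp <- config@waveParams
  y <- numeric(length(t))
  if (scale == 0) return(y)
  for (w in seq_len(nrow(wp))) {
    if (wp$ampMean[w] == 0) next
    comp <- waveUnitMeasure(config, wp$latMean[w], config@waveWidth[w])
    y <- y + wp$ampMean[w] / comp * scale *
      exp(-(t - wp$latMean[w])^2 / (2 * config@waveWidth[w]^2))
  }
  y
}

## Deterministic seed stream derived from a base seed; kept below 2^31.
deriveSeed <- function(seed, ...) {
  key <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in key) s <- (s * 69069 + as.double(k) * 7919 + 1) %% 2147483629
  as.integer(s)
}

#' Generate stimulus-locked ABR epochs for a monaural condition
#'
#' Each epoch is the noiseless wave template plus white Gaussian noise of SD
#' `config@noiseSd`; the template amplitude is scaled by the growth function
#' at the condition level. Identical `config`, `condition` and `seed` give
#' bit-identical epochs.
#'
#' @param config an [ABRSimConfig-class].
#' @param condition a monaural [StimulusCondition-class].
#' @param seed RNG seed; defaults to `config@seed`.
#' @param animalId provenance tag.
#' @return an [EpochSet-class].
#' @examples
#' cfg <- abrSimConfig("female", nEpochs = 50)
#' ep <- generateAbrEpochs(cfg, stimulusCondition("left", "click", level = 90))
#' @export
generateAbrEpochs <- function(config, condition = stimulusCondition(),
                              seed = config@seed, animalId = "sim") {
  validObject(config)
  validObject(condition)
  if (condition@ear == "binaural")
    stop("generateAbrEpochs() handles monaural conditions; ",
         "use generateBinauralSession() for binaural stimulation")
  tmpl <- abrTemplate(config, condition)
  n <- length(tmpl)
  samples <- withr::with_seed(seed, {
    noise <- if (config@noiseSd > 0)
      matrix(stats::rnorm(config@nEpochs * n, 0, config@noiseSd),
             nrow = config@nEpochs)
    else matrix(0, config@nEpochs, n)
    sweep(noise, 2, tmpl, "+")
  })
  new("EpochSet", samples = samples, fs = config@fs, condition = condition,
      animalId = animalId, seed = as.integer(seed))
}

## DN1 parameter lookup at one on-grid ITD.
bicParamsAt <- function(config, itd) {
  bp <- config@bicParams
  i <- which(abs(bp$itd - itd) < 1e-9)
  if (!length(i))
    stop("itd ", itd, " ms is not on the configured DN1 parameter grid")
  bp[i, , drop = FALSE]
}

#' Generate a binaural ABR session across ITDs
#'
#' For each requested ITD, generates left-ear and right-ear monaural epoch
#' sets plus a binaural epoch set whose mean response equals the sum of the
#' two monaural templates with a negative Gaussian DN1 deflection injected at
#' the configured amplitude and latency for that ITD. The binaural
#' interaction component recovered as binaural - (left + right) is therefore
#' the injected deflection (plus noise).
#'
#' @param config an [ABRSimConfig-class]; its `bicParams` table supplies the
#'   DN1 amplitude (uV) and latency (ms) per ITD.
#' @param itds numeric, ITDs in ms; must lie on the config's DN1 grid.
#' @param level presentation level in dB SPL.
#' @param seed base RNG seed; per-ITD streams are derived from it.
#' @param animalId provenance tag.
#' @return named list, one element per ITD (name = ITD in ms), each a list
#'   with elements `left`, `right`, `binaural` ([EpochSet-class] objects).
#' @export
generateBinauralSession <- function(config, itds = itdGrid(), level = 90,
                                    seed = config@seed, animalId = "sim") {
  validObject(config)
  off <- vapply(itds, function(x) min(abs(x - .ITD_GRID)), numeric(1))
  if (any(off > 1e-9))
    stop("itds must lie on the -2..+2 ms grid in 0.5 ms steps")
  t <- epochTime(config)
  out <- vector("list", length(itds))
  names(out) <- as.character(itds)
  for (k in seq_along(itds)) {
    itd <- itds[k]
    condL <- stimulusCondition("left", "click", level = level)
    condR <- stimulusCondition("right", "click", level = level)
    condB <- stimulusCondition("binaural", "click", level = level, itd = itd)
    left <- generateAbrEpochs(config, condL,
                              seed = deriveSeed(seed, k, 1), animalId = animalId)
    right <- generateAbrEpochs(config, condR,
                               seed = deriveSeed(seed, k, 2), animalId = animalId)
    bp <- bicParamsAt(config, itd)
    if (bp$ampMean < 0) stop("DN1 amplitude must be >= 0")
    # DN1 amplitude is measured as the filtered deflection magnitude re the
    # zero baseline; pre-compensate the injected dip the same way as waves
    dn1Comp <- if (bp$ampMean > 0) {
      g <- exp(-(t - bp$latMean)^2 / (2 * config@dn1Width^2))
      max(bandpassFilter(g, fs = config@fs))
    } else 1
    tmplB <- abrTemplate(config, condL) + abrTemplate(config, condR) -
      bp$ampMean / dn1Comp * exp(-(t - bp$latMean)^2 / (2 * config@dn1Width^2))
    n <- length(tmplB)
    sB <- deriveSeed(seed, k, 3)
    samples <- withr::with_seed(sB, {
      noise <- if (config@noiseSd > 0)
        matrix(stats::rnorm(config@nEpochs * n, 0, config@noiseSd),
               nrow = config@nEpochs)
      else matrix(0, config@nEpochs, n)
      sweep(noise, 2, tmplB, "+")
    })
    binaural <- new("EpochSet", samples = samples, fs = config@fs,
                    condition = condB, animalId = animalId,
                    seed = as.integer(sB))
    out[[k]] <- list(left = left, right = right, binaural = binaural)
  }
  out
}

#' Generate a descending level series
#'
#' One epoch set per level; the template amplitude is scaled by
#' `config@growth(level, trueThreshold)` and is exactly zero below the
#' generating threshold.
#'
#' @param config an [ABRSimConfig-class].
#' @param levels numeric, dB SPL, strictly descending in 10 dB steps.
#' @param condition a monaural [StimulusCondition-class]; its level is
#'   replaced by each series level in turn.
#' @param trueThreshold generating threshold in dB SPL; defaults to the
#'   config value.
#' @param seed base RNG seed.
#' @param animalId provenance tag.
#' @return named list level -> [EpochSet-class].
#' @export
generateLevelSeries <- function(config, levels,
                                condition = stimulusCondition(),
                                trueThreshold = config@trueThreshold,
                                seed = config@seed, animalId = "sim") {
  if (!length(levels)) stop("levels must be non-empty")
  if (length(levels) > 1 && any(abs(diff(levels) + 10) > 1e-9))
    stop("levels must descend in exact 10 dB steps")
  cfg <- config
  cfg@trueThreshold <- trueThreshold
  out <- vector("list", length(levels))
  names(out) <- as.character(levels)
  for (k in seq_along(levels)) {
    cond <- condition
    cond@level <- levels[k]
    out[[k]] <- generateAbrEpochs(cfg, cond, seed = deriveSeed(seed, 100, k),
                                  animalId = animalId)
  }
  out
}

#' Draw per-animal generator configurations
#'
#' Each simulated animal receives wave amplitudes drawn independently from
#' Normal(group mean, SE * sqrt(n)), truncated at zero; wave latencies drawn
#' with the same per-wave marginals but a single shared animal-level factor
#' (latencies across waves are strongly correlated within an animal, which
#' also preserves the strict wave ordering); a shared DN1 latency
#' offset drawn with the zero-ITD latency SD; and a shared DN1 amplitude
#' scale with the zero-ITD coefficient of variation (truncated at 0.1). The
#' shared offset/scale construction keeps each animal's DN1 latency minimal
#' and amplitude profile centred at zero ITD while reproducing the
#' between-animal spread of the group table at 0 ms.
#'
#' @param config an [ABRSimConfig-class] holding the group-level tables.
#' @param nAnimals number of animals to draw.
#' @param seed RNG seed.
#' @return list of [ABRSimConfig-class] objects, one per animal, with the SD
#'   columns zeroed (each animal's parameters are fixed).
#' @export
simulateAnimals <- function(config, nAnimals = 9L, seed = config@seed) {
  validObject(config)
  withr::with_seed(seed, {
    lapply(seq_len(nAnimals), function(a) {
      cfg <- config
      wp <- cfg@waveParams
      wp$ampMean <- pmax(stats::rnorm(nrow(wp), wp$ampMean, wp$ampSd), 0)
      # latencies share one animal-level factor: an animal that is slow on
      # one wave is slow on all (conduction speed, temperature, head size),
      # so lat_w = mean_w + z * sd_w with a single z per animal. This keeps
      # each wave's between-animal spread at the group value while
      # preserving the strict wave ordering.
      z <- stats::rnorm(1)
      lat <- wp$latMean + z * wp$latSd
      if (is.unsorted(lat, strictly = TRUE)) lat <- sort(lat)
      wp$latMean <- lat
      wp$ampSd <- 0
      wp$latSd <- 0
      cfg@waveParams <- wp

      bp <- cfg@bicParams
      i0 <- which(abs(bp$itd) < 1e-9)
      if (length(i0)) {
        latOff <- stats::rnorm(1, 0, bp$latSd[i0])
        cv <- if (bp$ampMean[i0] > 0) bp$ampSd[i0] / bp$ampMean[i0] else 0
        ampScale <- max(stats::rnorm(1, 1, cv), 0.1)
        bp$latMean <- bp$latMean + latOff
        bp$ampMean <- bp$ampMean * ampScale
        bp$ampSd <- 0
        bp$latSd <- 0
        cfg@bicParams <- bp
      }
      cfg@seed <- deriveSeed(seed, 7, a)
      cfg
    })
  })
}

#' Construct a logarithmic sweep specification
#'
#' @param fStart,fEnd endpoint frequencies, Hz (defaults 250 and 20000).
#' @param fs sampling rate, Hz (default 44100).
#' @param nPoints sweep length in samples (default 131072, "128k"; about 3 s
#'   at 44.1 kHz).
#' @param levelDbfs peak level re full scale, dB (default -15).
#' @return a [SweepSpec-class].
#' @export
sweepSpec <- function(fStart = 250, fEnd = 20000, fs = 44100,
                      nPoints = 131072L, levelDbfs = -15) {
  new("SweepSpec", fStart = fStart, fEnd = fEnd, fs = fs,
      nPoints = as.integer(nPoints), levelDbfs = levelDbfs)
}

#' Sweep duration in seconds
#'
#' @param spec a [SweepSpec-class].
#' @return numeric, `nPoints / fs`.
#' @export
sweepDuration <- function(spec) spec@nPoints / spec@fs

#' Synthesize a logarithmic (exponential) swept sine
#'
#' `x(t) = A sin(2 pi f1 L (exp(t/L) - 1))` with `L = T / log(f2/f1)`, so the
#' instantaneous frequency is `fStart` at t = 0 and `fEnd` at t = T. The peak
#' amplitude is `10^(levelDbfs/20)` re full scale.
#'
#' @param spec a [SweepSpec-class].
#' @return numeric vector of `spec@nPoints` samples.
#' @export
sweepSignal <- function(spec) {
  validObject(spec)
  T <- sweepDuration(spec)
  L <- T / log(spec@fEnd / spec@fStart)
  t <- (seq_len(spec@nPoints) - 1) / spec@fs
  amp <- 10^(spec@levelDbfs / 20)
  amp * sin(2 * pi * spec@fStart * L * (exp(t / L) - 1))
}

#' Construct a rigid-head model
#'
#' @param pinnaWidth,pinnaLength,interPinna mm.
#' @param maxIldDb ILD magnitude reached at lateral positions well above the
#'   shadow corner frequency, dB (default 18, matching the 15-20 dB
#'   high-frequency ILDs seen in small-rodent measurements).
#' @param shadowCornerHz corner frequency of the shadow shaping, Hz.
#' @param soundSpeed m/s (default 343).
#' @return a [HeadModel-class].
#' @export
headModel <- function(pinnaWidth = 10.2, pinnaLength = 13.0,
                      interPinna = 15.4, maxIldDb = 18,
                      shadowCornerHz = 4000, soundSpeed = 343) {
  new("HeadModel", pinnaWidth = pinnaWidth, pinnaLength = pinnaLength,
      interPinna = interPinna, maxIldDb = maxIldDb,
      shadowCornerHz = shadowCornerHz, soundSpeed = soundSpeed)
}

#' Speaker grid angles of one axis
#'
#' @param step grid spacing in degrees (default 10).
#' @return numeric, -90 to +90 degrees.
#' @export
speakerGrid <- function(step = 10) seq(-90, 90, by = step)

#' Speaker grid bookkeeping over the two axes
#'
#' The measurement rig positions one movable speaker in 10 degree increments
#' on a horizontal and a vertical axis; each axis offers 19 positions, for
#' 361 potential measurement locations.
#'
#' @param step grid spacing in degrees (default 10).
#' @return named numeric with elements `horizontal`, `vertical`, `total`.
#' @export
speakerGridPositions <- function(step = 10) {
  perAxis <- length(speakerGrid(step))
  c(horizontal = perAxis, vertical = perAxis, total = perAxis^2)
}

## Frequency-dependent ILD of the head model at one azimuth (dB, right-left).
headIldDb <- function(head, freq, azimuthDeg) {
  shadow <- freq^2 / (freq^2 + head@shadowCornerHz^2)
  head@maxIldDb * sin(azimuthDeg * pi / 180) * shadow
}

## Maximum interaural delay of the head model, seconds.
headMaxItdSec <- function(head) {
  (head@pinnaWidth + head@interPinna) / 1000 / head@soundSpeed
}

#' Generate a synthetic binaural HRTF measurement scene
#'
#' Convolves the sweep with a rigid-head two-ear filter per azimuth: an
#' interaural delay following the sine-of-azimuth law with maximum
#' `(pinnaWidth + interPinna) / c`, split symmetrically across the ears
#' (right ear leads at positive azimuths), and a frequency-dependent level
#' shadow giving ILDs that reach `maxIldDb` at +/-90 degrees above the corner
#' frequency. Delays and gains are applied in the frequency domain, so
#' fractional-sample delays are exact. A no-head calibration recording (the
#' sweep at the common propagation delay, unit gain) is included.
#'
#' @param head a [HeadModel-class].
#' @param azimuthsDeg numeric, degrees on the -90..+90, 10 deg grid.
#' @param spec a [SweepSpec-class].
#' @param refDelaySec common speaker-to-ear propagation delay, s.
#' @param pad zero-padding in samples appended before filtering (avoids
#'   circular wrap of the delays).
#' @return an [HRTFScene-class].
#' @export
generateHrtfScene <- function(head, azimuthsDeg = speakerGrid(),
                              spec = sweepSpec(), refDelaySec = 0.001,
                              pad = 4096L) {
  validObject(head)
  validObject(spec)
  grid <- speakerGrid()
  if (!all(azimuthsDeg %in% grid))
    stop("azimuths must lie on the -90..+90 deg grid in 10 deg steps")
  x <- c(sweepSignal(spec), numeric(pad))
  N <- length(x)
  X <- stats::fft(x)
  nyq <- floor(N / 2)
  freq <- (0:nyq) * spec@fs / N
  maxItd <- headMaxItdSec(head)

  applyFilter <- function(gainDb, delaySec) {
    Hhalf <- 10^(gainDb / 20) * exp(-2i * pi * freq * delaySec)
    H <- complex(length.out = N)
    H[1:(nyq + 1)] <- Hhalf
    if (N %% 2 == 0) {
      H[nyq + 1] <- Re(Hhalf[nyq + 1])  # real Nyquist bin
      if (nyq > 1) H[(nyq + 2):N] <- Conj(Hhalf[nyq:2])
    } else if (nyq >= 1) H[(nyq + 2):N] <- Conj(Hhalf[(nyq + 1):2])
    Re(stats::fft(X * H, inverse = TRUE)) / N
  }

  left <- right <- vector("list", length(azimuthsDeg))
  for (k in seq_along(azimuthsDeg)) {
    az <- azimuthsDeg[k]
    s <- sin(az * pi / 180)
    ild <- headIldDb(head, freq, az)           # right - left, dB
    right[[k]] <- applyFilter(+ild / 2, refDelaySec - maxItd / 2 * s)
    left[[k]] <- applyFilter(-ild / 2, refDelaySec + maxItd / 2 * s)
  }
  calibration <- applyFilter(numeric(nyq + 1), refDelaySec)
  new("HRTFScene", azimuths = azimuthsDeg, left = left, right = right,
      calibration = calibration, sweep = spec, fs = spec@fs)
}
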