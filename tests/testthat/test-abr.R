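test_that("band-pass magnitude matches the analytic Butterworth response", {
  fs <- 97656.25
  t <- seq(0, 2, by = 1 / fs)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  # zero-phase (forward-backward) application squares the magnitude, so the
  # amplitude ratio equals the analog order-2 band-pass power response
  # 1 / (1 + X^4) with X = (f^2 - lo*hi) / (f (hi - lo)).
  closedForm <- function(f) {
    X <- (f^2 - 50 * 3000) / (f * (3000 - 50))
    1 / (1 + X^4)
  }
  x <- sin(2 * pi * 1000 * t)
  y <- bandpassFilter(x, fs = fs)
  ratio <- sqrt(mean(y[mid]^2)) / sqrt(mean(x[mid]^2))
  expect_lt(abs(ratio - closedForm(1000)) / closedForm(1000), 0.01)
  # deep in the stopband the attenuation is at least the single-pass value
  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpassFilter(x10, fs = fs)
  r10 <- sqrt(mean(y10[mid]^2)) / sqrt(mean(x10[mid]^2))
  expect_lt(r10, sqrt(closedForm(10)))
  expect_error(bandpassFilter(x, hi = 60000, fs = fs), "Nyquist")
})

test_that("filtering zero epochs returns zero epochs", {
  cfg <- quickConfig(nEpochs = 3L, noiseSd = 0)
  cfg@waveParams$ampMean <- rep(0, 4)
  ep <- generateAbrEpochs(cfg, stimulusCondition(), seed = 1)
  expect_true(all(epochMatrix(bandpassFilter(ep)) == 0))
})

test_that("zero-phase filtering leaves a symmetric pulse latency unbiased", {
  fs <- 97656.25
  t <- timeAxis(round(12 * fs / 1000), fs)
  pulse <- exp(-(t - 5)^2 / (2 * 0.15^2))
  y <- bandpassFilter(pulse, fs = fs)
  expect_lt(abs(t[which.max(y)] - t[which.max(pulse)]), 1000 / fs + 1e-12)
})

test_that("averaging epochs mean-centers and cancels as expected", {
  fs <- 1000
  v <- sin(2 * pi * 5 * (0:99) / fs) + 2
  cond <- stimulusCondition()
  same <- new("EpochSet", samples = rbind(v, v, v), fs = fs,
              condition = cond, animalId = "x", seed = 1L)
  tr <- averageEpochs(same)
  expect_equal(traceValues(tr), v - mean(v), tolerance = 1e-12)
  expect_equal(tr@baselineOffset, mean(v))
  opp <- new("EpochSet", samples = rbind(v, -v), fs = fs,
             condition = cond, animalId = "x", seed = 1L)
  expect_equal(max(abs(traceValues(averageEpochs(opp)))), 0)
  expect_error(averageEpochs(
    new("EpochSet", samples = matrix(0, 1, 4)[0, , drop = FALSE], fs = fs,
        condition = cond, animalId = "", seed = 1L)))
})

test_that("averaged noise residual follows sigma/sqrt(n)", {
  cfg <- quickConfig(nEpochs = 400L, noiseSd = 1)
  cfg@waveParams$ampMean <- rep(0, 4)
  ep <- generateAbrEpochs(cfg, stimulusCondition(), seed = 21)
  rms <- sqrt(mean(traceValues(averageEpochs(ep))^2))
  expect_lt(abs(rms - 0.05) / 0.05, 0.15)
})

test_that("peak detection agrees with the exhaustive-scan oracle", {
  set.seed(42)
  fs <- 97656.25
  windows <- defaultWaveWindows("female")
  for (rep in 1:15) {
    # smooth random traces: random bumps plus band-limited noise
    amps <- runif(4, 0.5, 5)
    lats <- sort(runif(4, 1.2, 5.5))
    tr <- gaussTrace(amps, lats, rep(runif(1, 0.1, 0.3), 4), fs = fs)
    v <- traceValues(tr) +
      as.numeric(stats::filter(rnorm(length(traceValues(tr)), 0, 0.2),
                               rep(1 / 40, 40), sides = 2, circular = TRUE))
    tr <- makeTrace(v, fs)
    t <- timeAxis(length(v), fs)
    got <- detectPeaks(tr, windows = windows, minProminence = 0)
    want <- oraclePeaks(traceValues(tr), t, windows)
    for (w in 1:4) {
      if (is.na(want$peakIdx[w])) {
        expect_false(got@peaks$present[w])
      } else {
        expect_equal(got@peaks$latency[w], t[want$peakIdx[w]])
        expect_equal(got@peaks$amplitude[w], want$amp[w])
      }
    }
  }
})

test_that("two-bump trace amplitudes equal brute-force peak minus min", {
  tr <- gaussTrace(c(3, 2), c(2.0, 3.0), c(0.15, 0.15))
  v <- traceValues(tr)
  t <- timeAxis(length(v), samplingRate(tr))
  got <- detectPeaks(tr, windows = data.frame(wave = c("I", "II"),
                                              lo = c(1.5, 2.6),
                                              hi = c(2.5, 3.5)),
                     minProminence = 0)
  p1 <- which(t >= 1.5 & t <= 2.5)
  i1 <- p1[which.max(v[p1])]
  p2 <- which(t >= 2.6 & t <= 3.5)
  i2 <- p2[which.max(v[p2])]
  expect_equal(got@peaks$amplitude[1], v[i1] - min(v[i1:i2]))
  expect_equal(got@peaks$amplitude[2], v[i2] - min(v[i2:length(v)]))
})

test_that("flat traces yield no detected waves", {
  tr <- makeTrace(rep(0, 1172))
  got <- detectPeaks(tr)
  expect_false(any(got@peaks$present))
})

test_that("noiseless synthetic latencies are recovered to sample resolution", {
  cfg <- quickConfig(nEpochs = 1L, noiseSd = 0)
  tr <- bandpassFilter(averageEpochs(
    generateAbrEpochs(cfg, stimulusCondition(), seed = 1)))
  ps <- detectPeaks(tr, windows = defaultWaveWindows("female"))
  expect_true(all(ps@peaks$present))
  dt <- 1000 / samplingRate(tr)
  expect_true(all(abs(ps@peaks$latency -
                      voleWaveParams("female")$latMean) < 1.5 * dt))
})

test_that("wave amplitudes are invariant to a constant epoch offset", {
  cfg <- quickConfig(nEpochs = 1L, noiseSd = 0)
  ep <- generateAbrEpochs(cfg, stimulusCondition(), seed = 1)
  shifted <- new("EpochSet", samples = epochMatrix(ep) + 5, fs = ep@fs,
                 condition = ep@condition, animalId = "x", seed = 1L)
  a <- detectPeaks(averageEpochs(ep), windows = defaultWaveWindows("female"))
  b <- detectPeaks(averageEpochs(shifted),
                   windows = defaultWaveWindows("female"))
  expect_equal(a@peaks$amplitude, b@peaks$amplitude, tolerance = 1e-9)
})

test_that("annotations keep, deselect and move as specified", {
  cfg <- quickConfig(nEpochs = 1L, noiseSd = 0)
  tr <- averageEpochs(generateAbrEpochs(cfg, stimulusCondition(), seed = 1))
  ps <- detectPeaks(tr, windows = defaultWaveWindows("female"))
  keep <- applyAnnotations(ps, annotationSet(c("I", "II", "III", "IV"),
                                             rep("keep", 4)), tr)
  expect_equal(keep@peaks, ps@peaks)
  des <- applyAnnotations(ps, annotationSet("III", "deselect"), tr)
  expect_false(des@peaks$present[3])
  expect_equal(des@peaks[-3, ], ps@peaks[-3, ])
  idx <- round(ps@peaks$latency[1] * samplingRate(tr) / 1000) + 1L + 2L
  mov <- applyAnnotations(ps, annotationSet("I", "move", idx), tr)
  expect_equal(mov@peaks$latency[1] - ps@peaks$latency[1],
               2 / samplingRate(tr) * 1000, tolerance = 1e-12)
  expect_error(applyAnnotations(ps, annotationSet("I", "move", 10^7), tr),
               "outside")
})

test_that("ear averaging takes per-wave means and carries single ears", {
  p <- data.frame(wave = c("I", "II", "III", "IV"),
                  present = c(TRUE, TRUE, TRUE, FALSE),
                  peakTime = c(1.9, 2.9, 3.6, NA), peakValue = c(3, 4, 2, NA),
                  troughValue = c(0, 0, 0, NA), amplitude = c(3, 4, 2, NA),
                  latency = c(1.9, 2.9, 3.6, NA), nEars = 1L)
  q <- p
  q$amplitude <- c(5, 4, 2, NA)
  q$latency <- c(2.1, 2.9, 3.6, NA)
  q$peakTime <- q$latency
  q$present[3] <- FALSE
  left <- new("PeakSet", peaks = p, animalId = "a", ear = "left")
  right <- new("PeakSet", peaks = q, animalId = "a", ear = "right")
  avg <- averageEars(left, right)
  expect_equal(avg@peaks$amplitude[1], 4)        # mean of 3 and 5
  expect_equal(avg@peaks$latency[1], 2.0)        # mean of 1.9 and 2.1
  expect_equal(avg@peaks$nEars[1], 2L)
  expect_true(avg@peaks$present[3])              # left-only wave carried
  expect_equal(avg@peaks$nEars[3], 1L)
  expect_equal(avg@peaks$amplitude[3], 2)
  expect_false(avg@peaks$present[4])             # absent in both
  same <- averageEars(left, left)
  expect_equal(same@peaks$amplitude, p$amplitude)
})

test_that("per-animal wave parameters are recovered from noisy sessions", {
  base <- abrSimConfig("female", nEpochs = 200L, noiseSd = 3)
  animals <- simulateAnimals(base, nAnimals = 3L, seed = 99)
  for (a in animals) {
    # windows centred on this animal's generating latencies: the check is on
    # the quantification machinery, not on population window coverage
    win <- defaultWaveWindows(centers = a@waveParams$latMean)
    quant <- function(s) {
      ep <- generateAbrEpochs(a, stimulusCondition("left", "click",
                                                   level = 90), seed = s)
      detectPeaks(averageEpochs(bandpassFilter(ep)), windows = win)
    }
    avg <- averageEars(quant(a@seed %% 100000L + 1L),
                       quant(a@seed %% 100000L + 2L))
    expect_true(avg@peaks$present[1])
    expect_lt(abs(avg@peaks$amplitude[1] - a@waveParams$ampMean[1]), 0.6)
    expect_lt(abs(avg@peaks$latency[4] - a@waveParams$latMean[4]), 0.06)
  }
})
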