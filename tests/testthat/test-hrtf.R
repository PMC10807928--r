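test_that("sweep deconvolution recovers delays and filter taps", {
  spec <- sweepSpec(nPoints = 16384L)
  x <- sweepSignal(spec)
  ir0 <- deconvolveSweep(x, spec)
  expect_equal(which.max(abs(traceValues(ir0))), 1L)  # lag 0
  # pure delay of 100 samples: peak position and unity in-band magnitude
  # (the window keeps the pre-ringing of the band-limited impulse)
  ird <- deconvolveSweep(c(numeric(100), x), spec)
  expect_equal(which.max(abs(traceValues(ird))), 101L)
  Hd <- Mod(stats::fft(traceValues(ird)[1:4096]))
  fd <- (0:4095) * spec@fs / 4096
  inbd <- fd > 1000 & fd < 15000
  expect_lt(stats::median(abs(Hd[inbd] - 1)), 0.01)
  expect_lt(max(abs(Hd[inbd] - 1)), 0.05)
  # known 2-tap filter: in-band frequency response recovered within 1%
  taps <- c(1, 0.5)
  rec <- as.numeric(stats::filter(c(numeric(50), x), taps, sides = 1))
  rec[is.na(rec)] <- 0
  ir <- traceValues(deconvolveSweep(rec, spec))
  nfft <- 4096L
  seg <- ir[1:nfft]
  H <- stats::fft(seg)
  f <- (0:(nfft - 1)) * spec@fs / nfft
  Href <- stats::fft(c(numeric(50), taps, numeric(nfft - 52)))
  inband <- f > 1000 & f < 15000
  relerr <- Mod(H[inband] - Href[inband]) / Mod(Href[inband])
  expect_lt(stats::median(relerr), 0.01)
  expect_lt(max(relerr), 0.05)
  expect_error(deconvolveSweep(numeric(0), spec), "non-empty")
})

test_that("gain arithmetic subtracts calibration in dB", {
  g <- function(db) new("GainSpectrum", freq = seq(0, 22050, length.out = 257),
                        gainDb = rep(db, 257), smoothing = "raw",
                        nfft = 512L)
  expect_true(all(computeGain(g(10), g(10))@gainDb == 0))
  expect_true(all(computeGain(g(16), g(10))@gainDb == 6))
  bad <- new("GainSpectrum", freq = seq(0, 22050, length.out = 128),
             gainDb = numeric(128), smoothing = "raw", nfft = 256L)
  expect_error(computeGain(g(0), bad), "grids")
})

test_that("fractional-octave smoothing preserves flats and kernel mass", {
  freq <- seq(0, 22050, length.out = 4097)
  flat <- new("GainSpectrum", freq = freq, gainDb = rep(7, 4097),
              smoothing = "raw", nfft = 8192L)
  sm <- octaveSmooth(flat, 1 / 48)
  expect_equal(sm@gainDb, flat@gainDb, tolerance = 1e-9)
  expect_match(sm@smoothing, "1/48")
  # single-bin spike: power mass conserved within 1% (kernel integral)
  spike <- flat
  spike@gainDb <- rep(-120, 4097)
  i0 <- which.min(abs(freq - 8000))
  spike@gainDb[i0] <- 0
  smsp <- octaveSmooth(spike, 1 / 6)
  massIn <- sum(10^(spike@gainDb[-1] / 10))
  massOut <- sum(10^(smsp@gainDb[-1] / 10))
  expect_lt(abs(massOut - massIn) / massIn, 0.01)
  # smoothing twice at 1/48 ~ once at sqrt(2)/48 (variance additivity)
  set.seed(8)
  rough <- flat
  rough@gainDb <- as.numeric(stats::filter(rnorm(4097, 0, 3), rep(1 / 9, 9),
                                           circular = TRUE))
  twice <- octaveSmooth(octaveSmooth(rough, 1 / 48), 1 / 48)
  once <- octaveSmooth(rough, sqrt(2) / 48)
  keep <- freq > 2000 & freq < 18000
  expect_lt(max(abs(twice@gainDb[keep] - once@gainDb[keep])), 0.1)
  expect_error(octaveSmooth(flat, 0), "positive")
})

test_that("DTFs are the gains minus the across-position mean", {
  freq <- seq(0, 22050, length.out = 257)
  mk <- function(db) new("GainSpectrum", freq = freq,
                         gainDb = rep(db, 257), smoothing = "raw",
                         nfft = 512L)
  same <- computeDtf(replicate(5, mk(4)))
  for (d in same) expect_true(all(abs(d@gainDb) < 1e-12))
  # 19 positions, one +19 dB at every frequency, the rest 0
  gains <- c(list(mk(19)), replicate(18, mk(0)))
  dtf <- computeDtf(gains)
  expect_equal(dtf[[1]]@gainDb[10], 18)
  expect_equal(dtf[[2]]@gainDb[10], -1)
  # per-frequency mean over positions is 0 dB
  m <- rowMeans(vapply(dtf, function(g) g@gainDb, numeric(257)))
  expect_lt(max(abs(m)), 0.01)
  expect_error(computeDtf(list(mk(0))), "two positions")
})

test_that("ILD is right minus left in dB", {
  freq <- seq(0, 22050, length.out = 257)
  mk <- function(db) new("GainSpectrum", freq = freq, gainDb = db,
                         smoothing = "raw", nfft = 512L)
  expect_true(all(computeIld(mk(rep(3, 257)), mk(rep(3, 257)))@gainDb == 0))
  expect_true(all(computeIld(mk(rep(9, 257)), mk(rep(3, 257)))@gainDb == 6))
})

test_that("cross-correlation ITD matches construction and the lag oracle", {
  fs <- 44100
  t <- (0:511) / fs
  p <- exp(-((t - 0.005) / 0.0002)^2)
  mkIr <- function(v) new("ImpulseResponse", values = v, fs = fs)
  expect_equal(estimateItd(mkIr(p), mkIr(p)), 0)
  # right delayed by 0.1 ms => right lags => negative ITD
  d <- round(0.1e-3 * fs)  # not integer; use exact fractional via shift below
  pR <- exp(-((t - 0.005 - 0.1e-3) / 0.0002)^2)
  itd <- estimateItd(mkIr(p), mkIr(pR))
  expect_lt(abs(itd - (-0.1)), 1000 / fs / 4)
  expect_error(estimateItd(mkIr(numeric(512)), mkIr(p)), "zero")
  # integer-lag equality with the exhaustive oracle on random IR pairs
  set.seed(12)
  for (i in 1:5) {
    L <- rnorm(300)
    R <- rnorm(300)
    K <- 40L
    got <- estimateItd(mkIr(L), mkIr(R), maxLagMs = K / fs * 1000,
                       interpolate = FALSE, trim = FALSE)
    expect_equal(round(got * fs / 1000), oracleItdLag(L, R, K))
  }
})

test_that("synthetic scene pipeline recovers the lateral 80 us delay", {
  head <- headModel(pinnaWidth = 12.04, interPinna = 15.4)  # 27.44 mm path
  expect_equal(predictMaxItd(head), 80, tolerance = 1e-6)
  spec <- sweepSpec(nPoints = 32768L)
  scene <- generateHrtfScene(head, c(-90, 90), spec = spec)
  fs <- samplingRate(scene)
  itds <- vapply(seq_along(azimuths(scene)), function(k) {
    estimateItd(deconvolveSweep(scene@left[[k]], spec),
                deconvolveSweep(scene@right[[k]], spec))
  }, numeric(1))
  # +/-80 us within one sample at 44.1 kHz, odd in azimuth
  expect_lt(abs(itds[2] - 0.080), 1000 / fs)
  expect_lt(abs(itds[1] + 0.080), 1000 / fs)
  expect_lt(abs(itds[1] + itds[2]), 1000 / fs / 4)
})

test_that("full cue extraction has zero-mean DTFs and odd ILD/ITD", {
  head <- headModel()
  spec <- sweepSpec(nPoints = 16384L)
  scene <- generateHrtfScene(head, c(-90, -20, 20, 90), spec = spec)
  cues <- hrtfCues(scene, smoothFraction = NULL)
  # per-frequency mean of DTF across positions is 0 dB (within 0.01)
  expect_lt(max(abs(rowMeans(cues@dtfLeft))), 0.01)
  expect_lt(max(abs(rowMeans(cues@dtfRight))), 0.01)
  # ILD odd symmetry within 0.5 dB over the measured band
  keep <- cues@freq > 500 & cues@freq < 18000
  expect_lt(max(abs(cues@ild[keep, 1] + cues@ild[keep, 4])), 0.5)
  expect_lt(max(abs(cues@ild[keep, 2] + cues@ild[keep, 3])), 0.5)
  # ITD odd symmetry within a quarter sample
  fs <- samplingRate(scene)
  expect_lt(abs(cues@itdMs[1] + cues@itdMs[4]), 1000 / fs / 4)
  # lateral ILD approaches the configured maximum at high frequencies
  hi <- cues@freq > 12000 & cues@freq < 18000
  expect_gt(mean(cues@ild[hi, 4]), 0.7 * head@maxIldDb)
})

test_that("morphometry arithmetic: max ITD, path length, diameter", {
  # male group means: 10.7 + 15.3 mm over 343 m/s
  expect_equal(predictMaxItd(10.7, 15.3), 75.8, tolerance = 0.05)
  expect_equal(predictMaxItd(0, 0), 0)
  # round trip through the path-length inverse
  w <- 27.44
  expect_lt(abs(pathLengthForItd(predictMaxItd(w / 2, w / 2)) - w), 1e-9)
  expect_error(predictMaxItd(10, 10, soundSpeed = -1), "positive")
  # effective diameter: equal-area circle
  expect_equal(round(effectiveDiameter(13.0, 10.2), 1), 11.5)
  expect_equal(effectiveDiameter(7, 7), 7)
  expect_equal(effectiveDiameter(14.5, 9.2), sqrt(133.4), tolerance = 1e-12)
  expect_error(effectiveDiameter(-1, 5), "positive")
})
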