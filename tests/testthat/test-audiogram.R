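test_that("midpoint rule reproduces the worked example and censors", {
  r <- thresholdFromDecisions(c(60, 50), c(TRUE, FALSE))
  expect_equal(r$threshold, 55)
  expect_equal(r$censored, "none")
  expect_equal(thresholdFromDecisions(c(90, 80), c(TRUE, TRUE))$censored,
               "below_min")
  expect_equal(thresholdFromDecisions(c(90, 80), c(FALSE, FALSE))$censored,
               "above_max")
  expect_warning(
    r2 <- thresholdFromDecisions(c(90, 80, 70, 60), c(TRUE, FALSE, TRUE,
                                                      FALSE)),
    "non-monotone")
  expect_equal(r2$threshold, 85)
})

test_that("thresholds from multiple-of-10 levels always end in 5", {
  set.seed(5)
  for (i in 1:30) {
    levels <- seq(90, 20, by = -10)
    present <- sort(runif(length(levels)) > 0.5, decreasing = TRUE)
    r <- suppressWarnings(thresholdFromDecisions(levels, present))
    if (r$censored == "none") expect_equal(r$threshold %% 10, 5)
  }
})

test_that("presence score is a scale-invariant ratio", {
  cfg <- quickConfig(nEpochs = 50L, noiseSd = 1)
  tr <- averageEpochs(generateAbrEpochs(cfg, stimulusCondition(), seed = 2))
  s1 <- responsePresent(tr)
  tr3 <- makeTrace(traceValues(tr) * 3, samplingRate(tr))
  s3 <- responsePresent(tr3)
  expect_equal(s1$score, s3$score, tolerance = 1e-9)
  expect_true(s1$present)  # noiseless-template-dominated trace
  flat <- makeTrace(rep(0, 1172))
  expect_error(responsePresent(flat), "degenerate")
})

test_that("presence decisions match a directly computed score", {
  # independent oracle: peak-to-peak ratio computed with plain arithmetic
  cfg <- quickConfig(nEpochs = 30L, noiseSd = 1)
  cfg@waveParams$ampMean <- rep(0, 4)  # noise-only traces
  agree <- 0L
  fp <- 0L
  n <- 100L
  for (i in seq_len(n)) {
    tr <- averageEpochs(generateAbrEpochs(cfg, stimulusCondition(),
                                          seed = 1000 + i))
    v <- traceValues(tr)
    t <- timeAxis(length(v), samplingRate(tr))
    resp <- v[t >= 1 & t <= 8]
    noise <- v[t >= max(t) - 2]
    oracleScore <- (max(resp) - min(resp)) / (max(noise) - min(noise))
    got <- responsePresent(tr, criterion = 2)
    expect_equal(got$score, oracleScore, tolerance = 1e-9)
    if (got$present == (oracleScore >= 2)) agree <- agree + 1L
    if (got$present) fp <- fp + 1L
  }
  expect_equal(agree, n)
  # false-positive rate within binomial error of the oracle-measured rate
  # (identical decisions imply identical rates; sanity-check it is a rate)
  expect_lte(fp / n, 1)
})

test_that("estimated threshold recovers the generating threshold", {
  # high-SNR series: true threshold 55 -> estimate exactly 55
  cfg <- quickConfig(nEpochs = 80L, noiseSd = 0.5, trueThreshold = 55)
  levels <- seq(90, 10, by = -10)
  eps <- generateLevelSeries(cfg, levels, seed = 4)
  traces <- lapply(eps, function(e) bandpassFilter(averageEpochs(e)))
  r <- estimateThreshold(levelSeries(levels, traces))
  expect_equal(thresholdValue(r), 55)
  # true threshold 25 at 8 kHz: estimate within the 5 dB half-step bound
  cfg25 <- quickConfig(nEpochs = 80L, noiseSd = 0.5, trueThreshold = 25)
  eps25 <- generateLevelSeries(cfg25, levels,
                               stimulusCondition("left", "tone",
                                                 frequency = 8), seed = 5)
  traces25 <- lapply(eps25, function(e) bandpassFilter(averageEpochs(e)))
  r25 <- suppressWarnings(
    estimateThreshold(levelSeries(levels, traces25, label = "8")))
  expect_lte(abs(thresholdValue(r25) - 25), 5)
})

test_that("raising the criterion never lowers the estimated threshold", {
  levels <- seq(90, 10, by = -10)
  asNum <- function(r) {
    if (r@censored == "below_min") -Inf
    else if (r@censored == "above_max") Inf
    else r@threshold
  }
  for (seed in 1:5) {
    cfg <- quickConfig(nEpochs = 40L, noiseSd = 2, trueThreshold = 45,
                       seed = seed)
    eps <- generateLevelSeries(cfg, levels, seed = seed)
    traces <- lapply(eps, function(e) bandpassFilter(averageEpochs(e)))
    ls <- levelSeries(levels, traces)
    ests <- vapply(c(1.2, 2, 3, 5),
                   function(cr) asNum(suppressWarnings(
                     estimateThreshold(ls, criterion = cr))), numeric(1))
    expect_true(all(diff(ests) >= 0))
  }
})

test_that("audiograms assemble, locate best hearing and carry censoring", {
  mk <- function(th, cens = "none") new("ThresholdResult", threshold = th,
                                        censored = cens,
                                        decisions = data.frame(),
                                        label = "")
  res <- list(`1` = mk(45), `8` = mk(25), `32` = mk(30),
              `46` = mk(NA_real_, "above_max"))
  ag <- buildAudiogram(res)
  expect_equal(ag@frequencies, c(1, 8, 32, 46))
  expect_equal(bestFrequency(ag), 8)
  tab <- audiogramTable(ag)
  expect_equal(tab$censored, c("none", "none", "none", "above_max"))
  expect_true(is.na(tab$threshold_db_spl[4]))
  one <- buildAudiogram(list(`16` = mk(35)))
  expect_equal(length(one@frequencies), 1L)
  expect_error(buildAudiogram(list()), "non-empty")
})

test_that("per-frequency pipeline finds best sensitivity at 8 kHz", {
  # generating thresholds: male group means rounded to the 5 dB grid
  tab <- voleThresholds("male")
  levels <- seq(90, 10, by = -10)
  res <- list()
  for (f0 in c(1, 4, 8, 16, 32)) {
    thr <- round(tab$mean[tab$label == as.character(f0)] / 5) * 5
    cfg <- quickConfig(nEpochs = 40L, noiseSd = 0.5)
    eps <- generateLevelSeries(cfg, levels,
                               stimulusCondition("left", "tone",
                                                 frequency = f0),
                               trueThreshold = thr, seed = 60 + f0)
    traces <- lapply(eps, function(e) bandpassFilter(averageEpochs(e)))
    res[[as.character(f0)]] <- suppressWarnings(
      estimateThreshold(levelSeries(levels, traces, label = as.character(f0))))
  }
  ag <- buildAudiogram(res)
  expect_equal(bestFrequency(ag), 8)
  expect_equal(unname(thresholdValue(ag)[["8"]]), 25)
})
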