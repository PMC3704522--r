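mkTrace <- function(f, dt = 0.5, tApp = 30) {
  FluorescenceTrace(seq(0, by = dt, length.out = length(f)), f, tApp)
}

test_that("baseline estimation returns mean and sample SD of the window", {
  const <- mkTrace(rep(100, 200))
  expect_equal(estimateBaseline(const), list(baselineF0 = 100,
                                             baselineSd = 0))

  # hand arithmetic on a six-sample pre-stimulus window {98,100,102} x 2:
  # mean 100, SD sqrt(16/5)
  f <- rep(100, 200)
  f[55:60] <- c(98, 100, 102, 98, 100, 102)   # t in [27, 29.5]
  tr <- mkTrace(f)
  bl <- estimateBaseline(tr, kineticsConfig(baselineWindow = 3))
  expect_equal(bl$baselineF0, 100)
  expect_equal(bl$baselineSd, sqrt(16 / 5))

  # noiseless generator baseline is recovered exactly
  g <- simulateTrace(baselineF0 = 500, noiseSd = 0)
  expect_equal(estimateBaseline(g)$baselineF0, 500)
  expect_equal(estimateBaseline(g)$baselineSd, 0)

  # too few pre-stimulus samples
  shrt <- FluorescenceTrace(seq(0, 19.5, 0.5), rep(1, 40), tApp = 1)
  expect_error(estimateBaseline(shrt), "pre-stimulus")
})

test_that("onset detection finds the latency and flags non-responders", {
  const <- mkTrace(rep(100, 800))
  bl <- estimateBaseline(const)
  on <- detectOnset(const, bl)
  expect_false(on$responded)
  expect_true(is.na(on$responseTime))

  tr <- simulateTrace(baselineF0 = 100, latency = 14, noiseSd = 0)
  bl <- estimateBaseline(tr)
  on <- detectOnset(tr, bl)
  expect_true(on$responded)
  expect_equal(on$responseTime, 14, tolerance = 0.5)   # within one dt
})

test_that("peak metrics report amplitude and earliest-tie time to peak", {
  tr <- canonicalTrace()
  bl <- estimateBaseline(tr)
  on <- detectOnset(tr, bl)
  pk <- peakMetrics(tr, bl, on)
  expect_equal(pk$amplitude, 2450)
  expect_equal(pk$timeToPeak, 10, tolerance = 0.5)

  # a step that jumps and stays: the peak is the first elevated sample
  f <- c(rep(0, 100), rep(1, 100))
  tr2 <- mkTrace(f, tApp = 45)
  bl2 <- list(baselineF0 = 0, baselineSd = 0)
  on2 <- detectOnset(tr2, bl2, kineticsConfig(onsetAbsFloor = 0.5,
                                              onsetMinSamples = 3))
  pk2 <- peakMetrics(tr2, bl2, on2)
  expect_equal(pk2$tPeakAbs, 50)            # first sample of the plateau
  expect_lte(pk2$timeToPeak, 0.5)           # within one sample of onset

  expect_error(peakMetrics(tr, bl, list(responded = FALSE)), "onset")
})

test_that("maximal dF/dT is exact on a noiseless linear rise and 0 when flat", {
  tr <- canonicalTrace()
  bl <- estimateBaseline(tr)
  on <- detectOnset(tr, bl)
  pk <- peakMetrics(tr, bl, on)
  mr <- maxRate(tr, onsetTime = on$onsetTime, peakTime = pk$tPeakAbs)
  expect_equal(mr$maxRate, 245, tolerance = 1e-9)
  expect_false(mr$lowConfidence)

  expect_equal(maxRate(mkTrace(rep(7, 100)))$maxRate, 0)

  # a rise shorter than 3 samples is flagged low-confidence
  f <- c(rep(0, 70), 5, rep(10, 60))
  trs <- mkTrace(f, tApp = 30)
  mrs <- maxRate(trs, onsetTime = 35, peakTime = 35.5)
  expect_true(mrs$lowConfidence)
})

test_that("clearance times match exponential closed forms and censor properly", {
  tr <- canonicalTrace(decayTau = 30)
  bl <- estimateBaseline(tr)
  on <- detectOnset(tr, bl)
  pk <- peakMetrics(tr, bl, on)
  cl <- clearanceTimes(tr, bl, pk)
  expect_equal(cl$t25, 30 * log(4 / 3), tolerance = 0.25)
  expect_equal(cl$t50, 30 * log(2), tolerance = 0.25)
  expect_equal(cl$t90, 30 * log(10), tolerance = 0.25)
  expect_false(cl$t25Censored || cl$t50Censored || cl$t90Censored)

  # record truncated 10 s after the peak: t90 censored at the remaining 10 s
  short <- simulateTrace(baselineF0 = 100, tApp = 30, latency = 14,
                         riseSlope = 245, riseDuration = 10, decayTau = 30,
                         duration = 64, dt = 0.5, noiseSd = 0)
  bls <- estimateBaseline(short)
  ons <- detectOnset(short, bls)
  pks <- peakMetrics(short, bls, ons)
  cls <- clearanceTimes(short, bls, pks)
  expect_true(cls$t90Censored)
  expect_equal(cls$t90, 10, tolerance = 0.5)
  expect_false(cls$t25Censored)

  expect_error(clearanceTimes(tr, bl, list(amplitude = 0, tPeakAbs = 54)),
               "amplitude")
})

test_that("full analysis recovers every closed-form metric within one sample", {
  dt <- 0.5
  tr <- simulateTrace(baselineF0 = 100, tApp = 30, latency = 14,
                      riseSlope = 245, riseDuration = 10, decayTau = 60,
                      duration = 400, dt = dt, noiseSd = 0)
  m <- analyzeTransient(tr)
  expect_true(m$responded)
  expect_equal(m$response_time_s, 14, tolerance = dt)
  expect_equal(m$time_to_peak_s, 10, tolerance = dt)
  expect_equal(m$amplitude_fau, 2450, tolerance = 1e-9)
  expect_equal(m$max_rate_fau_per_s, 245, tolerance = 1e-9)
  expect_equal(m$t25_s, 60 * log(4 / 3), tolerance = dt)
  expect_equal(m$t50_s, 60 * log(2), tolerance = dt)
  expect_equal(m$t90_s, 60 * log(10), tolerance = dt)

  # constant trace: fully flagged no-response row, not an error
  flat <- analyzeTransient(mkTrace(rep(100, 800)))
  expect_false(flat$responded)
  expect_true(is.na(flat$amplitude_fau) && is.na(flat$t90_s))
})

test_that("batch analysis preserves order and labels", {
  traces <- lapply(1:40, function(i)
    simulateTrace(latency = 5 + i %% 7, noiseSd = 5, seed = i))
  out <- analyzeTraceBatch(traces, ids = sprintf("tr%02d", 1:40),
                           groups = rep(c("a", "b"), 20))
  expect_equal(nrow(out), 40)
  expect_equal(out$trace_id, sprintf("tr%02d", 1:40))
  expect_equal(out$group, rep(c("a", "b"), 20))
  expect_true(all(out$responded))
})

test_that("metrics obey scaling, shift and clearance-order invariants", {
  cfg <- kineticsConfig()
  for (seed in 1:5) {
    tr <- simulateTrace(baselineF0 = 200, latency = 6 + seed,
                        riseSlope = 100, riseDuration = 8, decayTau = 50,
                        noiseSd = 10, seed = seed)
    m <- analyzeTransient(tr, cfg)
    expect_true(m$t25_s <= m$t50_s && m$t50_s <= m$t90_s)

    # scaling fluorescence by c scales amplitude and rate, not the times;
    # the onset threshold floor must scale with the trace to be equivariant
    cc <- 3.7
    scl <- FluorescenceTrace(sampleTimes(tr), cc * intensities(tr),
                             stimulusTime(tr))
    ms <- analyzeTransient(scl, kineticsConfig(onsetAbsFloor = cc))
    expect_equal(ms$amplitude_fau, cc * m$amplitude_fau, tolerance = 1e-9)
    expect_equal(ms$max_rate_fau_per_s, cc * m$max_rate_fau_per_s,
                 tolerance = 1e-9)
    expect_equal(ms$response_time_s, m$response_time_s, tolerance = 1e-9)
    expect_equal(ms$t50_s, m$t50_s, tolerance = 1e-9)

    # shifting the time axis (and tApp with it) changes nothing
    sh <- FluorescenceTrace(sampleTimes(tr) + 17, intensities(tr),
                            stimulusTime(tr) + 17)
    mh <- analyzeTransient(sh, cfg)
    expect_equal(mh$response_time_s, m$response_time_s, tolerance = 1e-9)
    expect_equal(mh$t90_s, m$t90_s, tolerance = 1e-9)
    expect_equal(mh$amplitude_fau, m$amplitude_fau, tolerance = 1e-9)
  }

  # each clearance time is nondecreasing in decayTau on noiseless traces
  taus <- c(20, 40, 80, 160)
  cls <- t(sapply(taus, function(tau) {
    m <- analyzeTransient(canonicalTrace(decayTau = tau, duration = 600))
    c(m$t25_s, m$t50_s, m$t90_s)
  }))
  for (j in 1:3) expect_true(all(diff(cls[, j]) > 0))
})
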