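test_that("noiseless traces follow the piecewise closed form at every sample", {
  for (tau in c(30, 60, 115)) {
    tr <- simulateTrace(baselineF0 = 100, tApp = 30, latency = 14,
                        riseSlope = 245, riseDuration = 10, decayTau = tau,
                        duration = 400, dt = 0.5, noiseSd = 0)
    gt <- groundTruth(tr)
    expect_equal(intensities(tr),
                 closedFormTrace(sampleTimes(tr), 100, gt$tOn, gt$tPeak,
                                 245, tau),
                 tolerance = 1e-12)
  }
})

test_that("trace peak, pre-onset plateau and exponential half-life are exact", {
  tr <- simulateTrace(baselineF0 = 100, tApp = 30, latency = 14,
                      riseSlope = 245, riseDuration = 10, decayTau = 30,
                      duration = 400, dt = 0.5, noiseSd = 0)
  gt <- groundTruth(tr)
  tt <- sampleTimes(tr); ff <- intensities(tr)
  # peak sample: f0 + slope * riseDuration = 2550 at tPeak
  expect_equal(ff[which(tt == gt$tPeak)], 2550)
  expect_equal(gt$amplitude, 2450)
  # flat baseline before tApp + latency
  expect_true(all(ff[tt < gt$tOn] == 100))
  # half-life of the recovery: F(tPeak + tau*ln2) - f0 = A/2
  fHalf <- approx(tt, ff, xout = gt$tPeak + 30 * log(2))$y
  expect_equal(fHalf - 100, 2450 / 2, tolerance = 1e-3)
})

test_that("trace parameter violations are reported by field name", {
  expect_error(simulateTrace(latency = -1), "latency")
  expect_error(simulateTrace(dt = 0), "dt")
  expect_error(simulateTrace(duration = 30), "duration")
})

test_that("all three generators are bit-identical under a fixed seed", {
  a <- simulateTrace(noiseSd = 10, seed = 11)
  b <- simulateTrace(noiseSd = 10, seed = 11)
  expect_identical(intensities(a), intensities(b))

  ea <- simulateEMObjects(4, 0.5, 1, 0.2, 0.4, contactFraction = 0.5,
                          seed = 5)
  eb <- simulateEMObjects(4, 0.5, 1, 0.2, 0.4, contactFraction = 0.5,
                          seed = 5)
  expect_identical(ea, eb)

  ia <- simulateCellImage(nMito = 4, noiseSd = 0.01, seed = 9)
  ib <- simulateCellImage(nMito = 4, noiseSd = 0.01, seed = 9)
  expect_identical(ia$image, ib$image)
  expect_identical(ia$objects, ib$objects)
})

test_that("EM generator honours the contact fraction and size distribution", {
  # contactFraction 1 puts every row in the near range
  em <- simulateEMObjects(50, 0.8, 1, 0.6, 0.8, contactFraction = 1,
                          contactDistNear = c(0, 25),
                          contactDistFar = c(50, 400), seed = 2)
  expect_true(all(em$sr_distance_nm <= 25))
  expect_true(all(em$contact_truth))

  # mean 2-D size matches E[L]E[W] for independent uniforms; the analytic
  # value 0.63 um^2 is cross-checked by an independent Monte-Carlo draw
  set.seed(99)
  oracle <- mean(runif(2e5, 0.8, 1.0) * runif(2e5, 0.6, 0.8))
  expect_equal(oracle, 0.63, tolerance = 2e-3)
  big <- simulateEMObjects(10000, 0.8, 1.0, 0.6, 0.8, seed = 3)
  expect_equal(mean(big$size2d_um2), 0.63, tolerance = 0.005)

  expect_error(simulateEMObjects(10, 1, 0.5, 0.2, 0.4), "lengthLow")
  expect_error(simulateEMObjects(10, 0.5, 1, 0.2, 0.4,
                                 contactFraction = 1.2), "contactFraction")
})

test_that("cell image generator controls colocalization and geometry", {
  # colocLevel 1, no noise: ch2 equals ch1 exactly on mitochondrial pixels
  sim <- simulateCellImage(nMito = 4, colocLevel = 1, noiseSd = 0, seed = 4)
  mito <- sim$image[, , 1] > 0.4
  expect_equal(sim$image[, , 2][mito], sim$image[, , 1][mito])

  # colocLevel 0: channels are independent over mito pixels (rods render at
  # constant intensity, so a little noise is needed for ch1 to vary at all)
  sim0 <- simulateCellImage(imageShape = c(256, 256), nMito = 12,
                            colocLevel = 0, noiseSd = 0.02, seed = 6)
  m0 <- sim0$image[, , 1] > 0.4
  expect_gt(sum(m0), 500)
  r <- cor(sim0$image[, , 1][m0], sim0$image[, , 2][m0])
  expect_lt(abs(r), 0.1)

  # ground truth carries one row per rod with exact geometry fields
  expect_equal(nrow(sim$objects), 4)
  expect_true(all(c("center_row", "center_col", "theta_rad", "length_um",
                    "width_um", "contact_truth") %in% names(sim$objects)))

  # an impossible packing raises a capacity error
  expect_error(simulateCellImage(imageShape = c(48, 48), nMito = 200,
                                 lengthMean = 2, lengthSd = 0.1, seed = 1,
                                 maxTries = 20),
               "capacity")
})
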