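test_that("segmentation measures rectangles exactly and skips empty fields", {
  blank <- matrix(0, 64, 64)
  expect_equal(nrow(segmentMito(blank, 0.1, "fixed", threshold = 0.5)), 0)

  img <- matrix(0, 64, 64)
  img[21:40, 11:15] <- 1          # 20 x 5 px axis-aligned rectangle
  seg <- segmentMito(img, 0.1, "fixed", threshold = 0.5)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$length_um, 2.0)
  expect_equal(seg$width_um, 0.5)
  expect_equal(seg$size2d_um2, 1.0)
})

test_that("segmentation recovers synthetic rods, count and geometry", {
  sim <- simulateCellImage(nMito = 3, noiseSd = 0, seed = 3)
  seg <- segmentMito(sim$image[, , 1], sim$pixelSize, "fixed",
                     threshold = 0.4)
  expect_equal(nrow(seg), 3)
  tol <- 2 * sim$pixelSize        # within 2 px of generated lengths
  expect_equal(sort(seg$length_um), sort(sim$objects$length_um),
               tolerance = tol / min(sim$objects$length_um))

  # Otsu picks a sensible threshold on a bimodal noiseless field
  segO <- segmentMito(sim$image[, , 1], sim$pixelSize, "otsu")
  expect_equal(nrow(segO), 3)

  # object count equals ground truth across seeds (noiseless, non-overlap)
  for (s in 4:6) {
    sm <- simulateCellImage(nMito = 5, noiseSd = 0, seed = s)
    expect_equal(nrow(segmentMito(sm$image[, , 1], 0.1, "fixed",
                                  threshold = 0.4)), 5)
  }
})

test_that("2-D size is rotation invariant to within rasterization error", {
  # rod thick enough that the ~1-px rasterization uncertainty per dimension
  # stays inside the 5% band
  lenPx <- 64; widPx <- 32
  ref <- lenPx * widPx * 0.1^2
  for (theta in c(0, 20, 45, 70) * pi / 180) {
    m <- rasterRectOracle(128, 128, 64.3, 64.7, theta, lenPx, widPx)
    seg <- segmentMito(m, 0.1, "fixed", threshold = 0.5)
    expect_equal(nrow(seg), 1)
    expect_equal(seg$size2d_um2, ref, tolerance = 0.05)
  }
})

test_that("8-connected labeling joins diagonal pixels", {
  m <- matrix(0, 16, 16)
  m[cbind(3:8, 3:8)] <- 1         # a diagonal line is one object
  seg <- segmentMito(m, 0.1, "fixed", threshold = 0.5, minAreaPx = 2)
  expect_equal(nrow(seg), 1)
})

test_that("size statistics follow the mean/SE contract", {
  obj <- data.frame(id = 1:2, length_um = c(2, 4), width_um = c(1, 0.5))
  st <- sizeStats(obj)
  expect_equal(st$meanSize2d, 2.0)
  expect_equal(st$n, 2)

  one <- sizeStats(obj[1, ])
  expect_equal(one$se, 0)
  expect_true(one$singleObject)

  big <- simulateEMObjects(500, 0.8, 1.0, 0.6, 0.8, seed = 12)
  expect_equal(sizeStats(big)$meanSize2d, 0.63, tolerance = 0.03)

  expect_error(sizeStats(obj[0, ]), "at least one")
})

test_that("fused classification follows the area-fraction / length rule", {
  single <- data.frame(id = 1, length_um = 2, width_um = 1)
  expect_true(classifyFused(single)$fused)
  expect_equal(classifyFused(single)$largestFraction, 1)

  many <- data.frame(id = 1:20, length_um = rep(1, 20),
                     width_um = rep(0.5, 20))
  expect_false(classifyFused(many)$fused)

  # a long object alone triggers the length rule
  longOne <- rbind(many, data.frame(id = 21, length_um = 6, width_um = 0.5))
  expect_true(classifyFused(longOne)$fused)
  expect_error(classifyFused(many[0, ]), "no mitochondria")

  # fused fraction rises with the generator's length scale in every run
  fusedFrac <- function(lengthMean, seedBase) {
    mean(vapply(1:40, function(i) {
      cell <- simulateEMObjects(12, lengthMean * 0.7, lengthMean * 1.3,
                                0.3, 0.5, seed = seedBase + i)
      classifyFused(cell)$fused
    }, TRUE))
  }
  for (sb in c(100, 200, 300))
    expect_gt(fusedFrac(5, sb), fusedFrac(1, sb))
})

test_that("contact frequency follows the distance criterion", {
  zero <- data.frame(id = 1:5, length_um = 1, width_um = 0.5,
                     sr_distance_nm = 0)
  expect_equal(contactFrequency(contactSites(zero)), 1.0)

  three <- data.frame(id = 1:3, length_um = 1, width_um = 0.5,
                      sr_distance_nm = c(10, 20, 100))
  cs <- contactSites(three, dMaxNm = 30)
  expect_equal(cs@nContacts, 2L)
  expect_equal(contactFrequency(cs), 2 / 3)

  em <- simulateEMObjects(50, 0.8, 1, 0.6, 0.8, contactFraction = 0.94,
                          contactDistNear = c(0, 25),
                          contactDistFar = c(50, 400), seed = 8)
  expect_equal(contactFrequency(contactSites(em, 30)), 0.94)

  miss <- three; miss$sr_distance_nm[2] <- NA
  expect_error(contactSites(miss), "id 2")

  # nonincreasing in stricter dMax; frequency 1 at dMax = infinity-like
  grid <- c(5, 10, 20, 30, 60, 120, 1e9)
  freqs <- vapply(grid, function(d) contactFrequency(contactSites(em, d)),
                  numeric(1))
  expect_true(all(diff(freqs) >= 0))     # larger dMax never loses contacts
  expect_equal(freqs[length(freqs)], 1)
})

test_that("image SR distances match geometry and flag empty masks", {
  img <- matrix(0, 40, 40)
  img[10:20, 5:8] <- 1
  seg <- segmentMito(img, 0.1, "fixed", threshold = 0.5)

  # overlap: SR covering part of the object gives distance 0
  srOverlap <- matrix(FALSE, 40, 40); srOverlap[12:14, 6:10] <- TRUE
  d0 <- imageContactDistance(seg, srOverlap)
  expect_equal(d0$sr_distance_nm, 0)

  # SR 10 px from the object's boundary at 0.1 um/px is 1000 nm
  srFar <- matrix(FALSE, 40, 40); srFar[10:20, 18] <- TRUE
  d1 <- imageContactDistance(seg, srFar)
  expect_equal(d1$sr_distance_nm, 1000, tolerance = 1e-9)

  # empty mask: infinite distances plus the flag
  dInf <- imageContactDistance(seg, matrix(FALSE, 40, 40))
  expect_true(all(is.infinite(dInf$sr_distance_nm)))
  expect_true(attr(dInf, "emptySRMask"))
})

test_that("image SR distances equal the brute-force pixel-pair minimum", {
  set.seed(77)
  for (case in 1:25) {
    nr <- sample(12:32, 1); nc <- sample(12:32, 1)
    obj <- matrix(FALSE, nr, nc)
    r0 <- sample(2:(nr - 4), 1); c0 <- sample(2:(nc - 4), 1)
    obj[r0:min(nr, r0 + sample(2:6, 1)), c0:min(nc, c0 + sample(2:6, 1))] <- TRUE
    sr <- matrix(runif(nr * nc) < 0.06, nr, nc)
    seg <- segmentMito(obj * 1, 0.1, "fixed", threshold = 0.5,
                       minAreaPx = 1)
    got <- imageContactDistance(seg, sr)$sr_distance_nm
    want <- bruteMinDistOracle(obj, sr) * 0.1 * 1000
    expect_equal(got, want, tolerance = 1e-6)
  }
})
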