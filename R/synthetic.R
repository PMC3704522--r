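#' Simulate a caffeine-induced calcium transient
#'
#' Generates a fluorescence trace with the idealized transient shape used
#' throughout the package: a flat baseline until the stimulus plus an onset
#' latency, a linear rise of known slope and duration, and a single
#' exponential recovery back to baseline, with optional additive Gaussian
#' noise. Every kinetic quantity the analysis reports (latency, amplitude,
#' maximal dF/dT, clearance times) is analytically available from the
#' parameters and is attached to the trace as ground truth.
#'
#' The noiseless signal is
#' \deqn{F(t) = F_0}{F(t) = F0} for \eqn{t < t_{on}},
#' \deqn{F_0 + s (t - t_{on})} for \eqn{t_{on} \le t < t_{peak}}, and
#' \deqn{F_0 + A e^{-(t - t_{peak})/\tau}} for \eqn{t \ge t_{peak}},
#' with \eqn{t_{on} = t_{app} + latency}, \eqn{t_{peak} = t_{on} +
#' riseDuration} and amplitude \eqn{A = s \cdot riseDuration}.
#'
#' Defaults emulate the control-myotube condition: amplitude ~560 fau,
#' response latency 8 s, time to peak 8 s, maximal slope 70 fau/s, and a
#' recovery time constant chosen so the 50\% clearance time is ~80 s
#' (tau = 80 / ln 2). Sampling (dt = 0.5 s) and record length (400 s) are
#' package configuration, not measured values.
#'
#' @param baselineF0 resting fluorescence, fau.
#' @param tApp stimulus (caffeine) application time, s.
#' @param latency onset delay after application, s.
#' @param riseSlope linear rise slope, fau/s.
#' @param riseDuration rise time from onset to peak, s.
#' @param decayTau exponential recovery time constant, s.
#' @param duration record length, s.
#' @param dt sampling interval, s.
#' @param noiseSd additive Gaussian noise SD, fau.
#' @param seed optional integer; identical seed and parameters give
#'   bit-identical traces.
#' @return A \code{\linkS4class{FluorescenceTrace}} whose \code{groundTruth}
#'   list holds \code{latency}, \code{riseSlope}, \code{riseDuration},
#'   \code{amplitude}, \code{decayTau}, \code{tOn}, \code{tPeak} and the
#'   analytic clearance times \code{t25}, \code{t50}, \code{t90}
#'   (\eqn{\tau \ln(1/(1-q))} for q = 0.25, 0.5, 0.9).
#' @examples
#' tr <- simulateTrace(noiseSd = 0)
#' groundTruth(tr)$amplitude
#' @export
simulateTrace <- function(baselineF0 = 500, tApp = 30, latency = 8,
                          riseSlope = 70, riseDuration = 8,
                          decayTau = 80 / log(2), duration = 400, dt = 0.5,
                          noiseSd = 0, seed = NULL) {
  checkPositive(latency, "latency")
  checkPositive(riseSlope, "riseSlope")
  checkPositive(riseDuration, "riseDuration")
  checkPositive(decayTau, "decayTau")
  checkPositive(duration, "duration")
  checkPositive(dt, "dt")
  checkNonNegative(tApp, "tApp")
  checkNonNegative(noiseSd, "noiseSd")
  if (tApp + latency + riseDuration >= duration)
    stop("parameter 'duration' must exceed tApp + latency + riseDuration",
         call. = FALSE)

  time <- seq(0, duration, by = dt)
  tOn <- tApp + latency
  tPeak <- tOn + riseDuration
  amplitude <- riseSlope * riseDuration
  f <- transientShape(time, baselineF0, tOn, tPeak, riseSlope, decayTau)
  if (noiseSd > 0)
    f <- f + withSeed(seed, stats::rnorm(length(f), 0, noiseSd))

  truth <- list(
    baselineF0 = baselineF0, latency = latency, riseSlope = riseSlope,
    riseDuration = riseDuration, amplitude = amplitude, decayTau = decayTau,
    tOn = tOn, tPeak = tPeak, noiseSd = noiseSd, dt = dt,
    t25 = decayTau * log(1 / 0.75),
    t50 = decayTau * log(2),
    t90 = decayTau * log(10)
  )
  FluorescenceTrace(time, f, tApp, groundTruth = truth)
}

# Piecewise closed form of the noiseless transient.
transientShape <- function(time, f0, tOn, tPeak, slope, tau) {
  amplitude <- slope * (tPeak - tOn)
  f <- rep(f0, length(time))
  rise <- time >= tOn & time < tPeak
  f[rise] <- f0 + slope * (time[rise] - tOn)
  dec <- time >= tPeak
  f[dec] <- f0 + amplitude * exp(-(time[dec] - tPeak) / tau)
  f
}

#' Simulate an electron-microscopy style mitochondrion table
#'
#' Emulates the per-mitochondrion measurements scored on 2-D electron
#' micrographs: length and width drawn independently from uniform ranges, and
#' a distance to the nearest SR element structured so that a chosen fraction
#' of mitochondria lies within contact range. \code{round(contactFraction *
#' n)} rows draw their SR distance from the near range, the remainder from
#' the far range.
#'
#' @param n number of mitochondria.
#' @param lengthLow,lengthHigh uniform range for length, um.
#' @param widthLow,widthHigh uniform range for width, um.
#' @param contactFraction fraction in [0, 1] placed within contact distance.
#' @param contactDistNear length-2 SR-distance range (nm) for contact rows.
#' @param contactDistFar length-2 SR-distance range (nm) for the rest.
#' @param seed optional integer for reproducibility.
#' @return A data.frame with columns \code{id}, \code{length_um},
#'   \code{width_um}, \code{size2d_um2} (= length x width),
#'   \code{sr_distance_nm}, \code{contact_truth}.
#' @examples
#' em <- simulateEMObjects(50, 0.8, 1.0, 0.6, 0.8, contactFraction = 0.94,
#'                         seed = 1)
#' mean(em$size2d_um2)
#' @export
simulateEMObjects <- function(n, lengthLow, lengthHigh, widthLow, widthHigh,
                              contactFraction = 0,
                              contactDistNear = c(0, 25),
                              contactDistFar = c(50, 400),
                              seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("parameter 'n' must be >= 1", call. = FALSE)
  n <- as.integer(n)
  checkRange(lengthLow, lengthHigh, "lengthLow", "lengthHigh")
  checkRange(widthLow, widthHigh, "widthLow", "widthHigh")
  checkProportion(contactFraction, "contactFraction")
  stopifnot(length(contactDistNear) == 2L, length(contactDistFar) == 2L)

  withSeed(seed, {
    len <- stats::runif(n, lengthLow, lengthHigh)
    wid <- stats::runif(n, widthLow, widthHigh)
    nNear <- as.integer(round(contactFraction * n))
    dist <- numeric(n)
    contact <- rep(FALSE, n)
    if (nNear > 0L) {
      dist[seq_len(nNear)] <- stats::runif(nNear, contactDistNear[1L],
                                           contactDistNear[2L])
      contact[seq_len(nNear)] <- TRUE
    }
    if (nNear < n)
      dist[(nNear + 1L):n] <- stats::runif(n - nNear, contactDistFar[1L],
                                           contactDistFar[2L])
    data.frame(
      id = seq_len(n),
      length_um = pmax(len, wid),
      width_um = pmin(len, wid),
      size2d_um2 = len * wid,
      sr_distance_nm = dist,
      contact_truth = contact
    )
  })
}

#' Simulate a two-channel cell image with ground truth
#'
#' Renders a field of non-overlapping rod-shaped "mitochondria" (channel 1)
#' and an SR-like blob texture (channel 2) with a controllable
#' colocalization level and contact structure, returning exact per-rod
#' ground truth. Rods are rasterized as binary rotated rectangles (no
#' anti-aliasing) so that the generated geometry is exact; a chosen fraction
#' of rods receives an SR blob placed immediately adjacent to it (a contact),
#' the remaining SR blobs are kept away from all rods.
#'
#' Channel 2 equals the SR texture away from mitochondria; on mitochondrial
#' pixels it is \code{colocLevel * ch1 + (1 - colocLevel) * texture}, so
#' \code{colocLevel = 1} makes the channels identical over mitochondria and
#' \code{colocLevel = 0} makes them independent there.
#'
#' @param imageShape integer(2), image size in pixels (rows, cols).
#' @param pixelSize pixel size, um/px.
#' @param nMito number of rods to place.
#' @param lengthMean,lengthSd rod length distribution (normal, truncated
#'   below at the rod width), um.
#' @param widthMean rod width, um.
#' @param contactFraction fraction of rods given an adjacent SR blob.
#' @param colocLevel channel-2 mixing weight on mitochondrial pixels, [0, 1].
#' @param noiseSd additive Gaussian noise SD (intensity units; images are on
#'   a [0, 1] intensity scale).
#' @param nBackgroundBlobs SR blobs placed away from all rods.
#' @param seed optional integer for reproducibility.
#' @param maxTries placement retries per rod before a capacity error.
#' @return A list with \code{image} (rows x cols x 2 array), \code{srMask}
#'   (binary SR foreground used for contact geometry), and \code{objects}, a
#'   data.frame of ground truth (id, center_row, center_col, theta_rad,
#'   length_um, width_um, contact_truth).
#' @examples
#' sim <- simulateCellImage(nMito = 3, seed = 1)
#' dim(sim$image)
#' @export
simulateCellImage <- function(imageShape = c(192L, 192L), pixelSize = 0.1,
                              nMito = 10, lengthMean = 1.5, lengthSd = 0.4,
                              widthMean = 0.5, contactFraction = 0.3,
                              colocLevel = 0.5, noiseSd = 0,
                              nBackgroundBlobs = 15, seed = NULL,
                              maxTries = 400L) {
  checkPositive(pixelSize, "pixelSize")
  checkProportion(contactFraction, "contactFraction")
  checkProportion(colocLevel, "colocLevel")
  checkNonNegative(noiseSd, "noiseSd")
  if (!is.numeric(nMito) || nMito < 1)
    stop("parameter 'nMito' must be >= 1", call. = FALSE)
  nMito <- as.integer(nMito)
  nr <- as.integer(imageShape[1L]); nc <- as.integer(imageShape[2L])

  withSeed(seed, {
    occupied <- matrix(FALSE, nr, nc)   # rods dilated by a 2-px margin
    mitoMask <- matrix(FALSE, nr, nc)
    truth <- vector("list", nMito)
    widPx <- widthMean / pixelSize
    for (i in seq_len(nMito)) {
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        lenUm <- stats::rnorm(1, lengthMean, lengthSd)
        if (lenUm < widthMean) next
        lenPx <- lenUm / pixelSize
        theta <- stats::runif(1, 0, pi)
        margin <- lenPx / 2 + widPx / 2 + 3
        if (2 * margin >= min(nr, nc))
          stop("capacity error: a rod cannot fit within the frame",
               call. = FALSE)
        cr <- stats::runif(1, margin, nr - margin)
        cc <- stats::runif(1, margin, nc - margin)
        px <- rodPixels(cr, cc, theta, lenPx, widPx, nr, nc)
        if (nrow(px) == 0L) next
        grown <- dilatePixels(px, nr, nc, 2L)
        if (any(occupied[grown])) next
        occupied[grown] <- TRUE
        mitoMask[px] <- TRUE
        truth[[i]] <- data.frame(
          id = i, center_row = cr, center_col = cc, theta_rad = theta,
          length_um = lenUm, width_um = widthMean)
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf(
          "capacity error: could not place rod %d after %d tries", i,
          maxTries), call. = FALSE)
    }
    truth <- do.call(rbind, truth)

    nContact <- as.integer(round(contactFraction * nMito))
    truth$contact_truth <- seq_len(nMito) <= nContact

    # SR texture: soft blobs; one adjacent to each contact rod, the rest
    # kept >= 12 px away from every rod.
    srMask <- matrix(FALSE, nr, nc)
    blobCenters <- NULL
    for (i in seq_len(nContact)) {
      th <- truth$theta_rad[i]
      # axis direction is (sin th, cos th) in (row, col); step perpendicular
      # so the blob straddles the rod's long edge
      off <- truth$width_um[i] / pixelSize / 2 + 1.5
      s <- sample(c(-1, 1), 1)
      br <- truth$center_row[i] + s * off * cos(th)
      bc <- truth$center_col[i] - s * off * sin(th)
      blobCenters <- rbind(blobCenters, c(br, bc, 2.5))
    }
    mitoDist <- if (any(mitoMask))
      as.matrix(EBImage::distmap(EBImage::Image(1 - mitoMask)))
    else matrix(Inf, nr, nc)
    placedBg <- 0L; tries <- 0L
    while (placedBg < nBackgroundBlobs && tries < maxTries * 5L) {
      tries <- tries + 1L
      br <- stats::runif(1, 4, nr - 3); bc <- stats::runif(1, 4, nc - 3)
      if (mitoDist[round(br), round(bc)] < 12) next
      blobCenters <- rbind(blobCenters, c(br, bc, stats::runif(1, 2, 4)))
      placedBg <- placedBg + 1L
    }
    texture <- matrix(0, nr, nc)
    if (!is.null(blobCenters)) {
      rows <- matrix(seq_len(nr), nr, nc)
      cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      for (k in seq_len(nrow(blobCenters))) {
        d2 <- (rows - blobCenters[k, 1L])^2 + (cols - blobCenters[k, 2L])^2
        texture <- texture + 0.7 * exp(-d2 / (2 * blobCenters[k, 3L]^2))
      }
      srMask <- texture > 0.25
    }

    ch1 <- matrix(0.05, nr, nc)
    ch1[mitoMask] <- 0.8
    ch2 <- texture + 0.02
    ch2[mitoMask] <- colocLevel * ch1[mitoMask] +
      (1 - colocLevel) * (texture[mitoMask] + 0.02)
    if (noiseSd > 0) {
      ch1 <- ch1 + stats::rnorm(nr * nc, 0, noiseSd)
      ch2 <- ch2 + stats::rnorm(nr * nc, 0, noiseSd)
    }
    list(image = array(c(ch1, ch2), dim = c(nr, nc, 2L)),
         srMask = srMask, objects = truth, pixelSize = pixelSize)
  })
}

# Pixel-center rasterization of a rotated rectangle; returns an n x 2 matrix
# of (row, col) indices.
rodPixels <- function(cr, cc, theta, lenPx, widPx, nr, nc) {
  half <- ceiling(lenPx / 2 + widPx / 2) + 1L
  r0 <- max(1L, floor(cr - half)); r1 <- min(nr, ceiling(cr + half))
  c0 <- max(1L, floor(cc - half)); c1 <- min(nc, ceiling(cc + half))
  rs <- r0:r1; cs <- c0:c1
  rg <- matrix(rs, length(rs), length(cs))
  cg <- matrix(cs, length(rs), length(cs), byrow = TRUE)
  dr <- rg - cr; dc <- cg - cc
  u <- dc * cos(theta) + dr * sin(theta)
  v <- -dc * sin(theta) + dr * cos(theta)
  keep <- abs(u) <= lenPx / 2 & abs(v) <= widPx / 2
  cbind(rg[keep], cg[keep])
}

# 8-neighbourhood dilation of a pixel set by `by` pixels (chessboard).
dilatePixels <- function(px, nr, nc, by) {
  offs <- expand.grid(dr = -by:by, dc = -by:by)
  out <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
    cbind(px[, 1L] + offs$dr[k], px[, 2L] + offs$dc[k])))
  keep <- out[, 1L] >= 1L & out[, 1L] <= nr & out[, 2L] >= 1L & out[, 2L] <= nc
  unique(out[keep, , drop = FALSE])
}
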