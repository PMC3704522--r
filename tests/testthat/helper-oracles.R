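# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Two-sided Fisher p by direct enumeration of the hypergeometric family with
# the observed margins, probability-mass rule, pure combinatorics.
fisherEnumOracle <- function(tab) {
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L]); N <- sum(tab)
  xs <- max(0L, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(N, c1)
  pObs <- choose(r1, tab[1L, 1L]) * choose(r2, c1 - tab[1L, 1L]) /
    choose(N, c1)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

# Brute-force minimum Euclidean distance (pixel centers) between an object's
# boundary pixels and the SR foreground.
bruteMinDistOracle <- function(objMask, srMask) {
  nr <- nrow(objMask); nc <- ncol(objMask)
  isBoundary <- function(r, c) {
    if (r == 1L || r == nr || c == 1L || c == nc) return(TRUE)
    !(objMask[r - 1L, c] && objMask[r + 1L, c] &&
      objMask[r, c - 1L] && objMask[r, c + 1L])
  }
  op <- which(objMask, arr.ind = TRUE)
  keep <- vapply(seq_len(nrow(op)),
                 function(i) isBoundary(op[i, 1L], op[i, 2L]), TRUE)
  op <- op[keep, , drop = FALSE]
  sp <- which(srMask > 0, arr.ind = TRUE)
  if (nrow(sp) == 0L) return(Inf)
  best <- Inf
  for (i in seq_len(nrow(op)))
    best <- min(best, sqrt((op[i, 1L] - sp[, 1L])^2 +
                           (op[i, 2L] - sp[, 2L])^2))
  best
}

# Independent piecewise closed form of the noiseless transient.
closedFormTrace <- function(time, f0, tOn, tPeak, slope, tau) {
  A <- slope * (tPeak - tOn)
  ifelse(time < tOn, f0,
         ifelse(time < tPeak, f0 + slope * (time - tOn),
                f0 + A * exp(-(time - tPeak) / tau)))
}

# Canonical noiseless fused-condition trace used by several tests.
canonicalTrace <- function(dt = 0.5, noiseSd = 0, seed = NULL,
                           decayTau = 60, duration = 400) {
  simulateTrace(baselineF0 = 100, tApp = 30, latency = 14, riseSlope = 245,
                riseDuration = 10, decayTau = decayTau, duration = duration,
                dt = dt, noiseSd = noiseSd, seed = seed)
}

# Independent rasterization of a rotated rectangle (pixel centers inside).
rasterRectOracle <- function(nr, nc, cr, cc, theta, lenPx, widPx) {
  m <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    u <- (c - cc) * cos(theta) + (r - cr) * sin(theta)
    v <- -(c - cc) * sin(theta) + (r - cr) * cos(theta)
    if (abs(u) <= lenPx / 2 && abs(v) <= widPx / 2) m[r, c] <- 1
  }
  m
}
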