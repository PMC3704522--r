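#' @import methods
NULL

#' FluorescenceTrace: a sampled fluorescence time series with a stimulus time
#'
#' Container for a single-cell fluorescence recording (e.g. Fluo-4 loaded
#' myotubes) sampled on a uniform time grid, together with the known stimulus
#' (caffeine) application time. All kinetic analyses start from this class.
#'
#' @slot time numeric, sample times in seconds; strictly increasing, uniform.
#' @slot fluorescence numeric, fluorescence in arbitrary units (fau), same
#'   length as \code{time}.
#' @slot tApp numeric(1), stimulus application time in seconds; must lie
#'   within \code{[time[1], time[n])}.
#' @slot groundTruth list, optional generator ground truth (empty for real
#'   recordings); see \code{\link{simulateTrace}}.
#'
#' @seealso \code{\link{simulateTrace}}, \code{\link{analyzeTransient}}
#' @export
setClass("FluorescenceTrace",
  representation(
    time = "numeric",
    fluorescence = "numeric",
    tApp = "numeric",
    groundTruth = "list"
  )
)

setValidity("FluorescenceTrace", function(object) {
  msg <- character(0)
  tt <- object@time
  ff <- object@fluorescence
  if (length(tt) < 20L)
    msg <- c(msg, "a trace needs at least 20 samples")
  if (length(tt) != length(ff))
    msg <- c(msg, "'time' and 'fluorescence' must have equal length")
  if (anyNA(tt) || anyNA(ff))
    msg <- c(msg, "'time' and 'fluorescence' must not contain NA")
  if (length(tt) >= 2L) {
    dts <- diff(tt)
    if (any(dts <= 0))
      msg <- c(msg, "'time' must be strictly increasing")
    else if ((max(dts) - min(dts)) / mean(dts) >= 1e-6)
      msg <- c(msg, "'time' must be a uniform grid (relative jitter < 1e-6)")
  }
  if (length(object@tApp) != 1L || is.na(object@tApp))
    msg <- c(msg, "'tApp' must be a single finite number")
  else if (length(tt) >= 2L &&
           (object@tApp < tt[1L] || object@tApp >= tt[length(tt)]))
    msg <- c(msg, "'tApp' must lie within [time[1], time[n])")
  if (length(msg)) msg else TRUE
})

#' Construct a FluorescenceTrace
#'
#' @param time numeric vector of sample times (s), uniform ascending grid.
#' @param fluorescence numeric vector of intensities (fau).
#' @param tApp stimulus application time (s).
#' @param groundTruth optional list of generator ground-truth values.
#' @return A \code{\linkS4class{FluorescenceTrace}} object.
#' @examples
#' tr <- FluorescenceTrace(seq(0, 99, by = 1), rep(100, 100), tApp = 30)
#' nSamples(tr)
#' @export
FluorescenceTrace <- function(time, fluorescence, tApp, groundTruth = list()) {
  new("FluorescenceTrace", time = as.numeric(time),
      fluorescence = as.numeric(fluorescence),
      tApp = as.numeric(tApp), groundTruth = groundTruth)
}

#' LineScanProfile: paired channel intensities along a segment
#'
#' Intensity profiles of two channels sampled along a user-defined image
#' segment (the computational counterpart of the line scans drawn next to
#' dual-label confocal panels, e.g. Tom20 vs PDI).
#'
#' @slot positions numeric, distance along the segment in micrometres,
#'   strictly increasing from 0.
#' @slot ch1,ch2 numeric, channel intensities at \code{positions}.
#' @slot endpoints 2 x 2 numeric matrix, (row, col) pixel coordinates of the
#'   segment endpoints (1-based).
#' @slot widthPx integer(1), perpendicular averaging width in pixels (odd).
#' @seealso \code{\link{lineScan}}, \code{\link{profileCorrelation}}
#' @export
setClass("LineScanProfile",
  representation(
    positions = "numeric",
    ch1 = "numeric",
    ch2 = "numeric",
    endpoints = "matrix",
    widthPx = "integer"
  )
)

setValidity("LineScanProfile", function(object) {
  msg <- character(0)
  n <- length(object@positions)
  if (n < 2L)
    msg <- c(msg, "a profile needs at least 2 samples")
  if (length(object@ch1) != n || length(object@ch2) != n)
    msg <- c(msg, "'ch1' and 'ch2' must match 'positions' in length")
  if (n >= 1L && abs(object@positions[1L]) > 1e-12)
    msg <- c(msg, "'positions' must start at 0")
  if (n >= 2L && any(diff(object@positions) <= 0))
    msg <- c(msg, "'positions' must be strictly increasing")
  if (!all(dim(object@endpoints) == c(2L, 2L)))
    msg <- c(msg, "'endpoints' must be a 2 x 2 matrix")
  if (length(object@widthPx) != 1L || object@widthPx < 1L ||
      object@widthPx %% 2L == 0L)
    msg <- c(msg, "'widthPx' must be a single odd positive integer")
  if (length(msg)) msg else TRUE
})

#' TestResult: the outcome of a group-comparison test
#'
#' @slot testName character(1), e.g. "Student t (pooled)".
#' @slot statistic numeric(1), test statistic (NA for exact tests).
#' @slot df numeric, degrees of freedom (length 0, 1 or 2).
#' @slot pValue numeric(1) in (0, 1].
#' @export
setClass("TestResult",
  representation(
    testName = "character",
    statistic = "numeric",
    df = "numeric",
    pValue = "numeric"
  )
)

setValidity("TestResult", function(object) {
  msg <- character(0)
  p <- object@pValue
  if (length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    msg <- c(msg, "'pValue' must be a single number in (0, 1]")
  if (length(object@testName) != 1L)
    msg <- c(msg, "'testName' must be a single string")
  if (length(msg)) msg else TRUE
})

TestResult <- function(testName, statistic, df, pValue) {
  # guard against p = 1 + eps from floating-point tail sums
  new("TestResult", testName = testName, statistic = as.numeric(statistic),
      df = as.numeric(df), pValue = min(as.numeric(pValue), 1))
}

#' ContactSummary: SR:mitochondrial contact-site frequency
#'
#' The per-group contact readout: the number of mitochondria scored, the
#' number lying within the contact distance of SR, and their ratio (the
#' contact-site frequency).
#'
#' @slot nMito integer(1), mitochondria scored.
#' @slot nContacts integer(1), mitochondria with an SR contact.
#' @slot frequency numeric(1), \code{nContacts / nMito}.
#' @slot dMaxNm numeric(1), contact distance criterion used (nm).
#' @seealso \code{\link{contactSites}}
#' @export
setClass("ContactSummary",
  representation(
    nMito = "integer",
    nContacts = "integer",
    frequency = "numeric",
    dMaxNm = "numeric"
  )
)

setValidity("ContactSummary", function(object) {
  msg <- character(0)
  if (object@nMito < 1L)
    msg <- c(msg, "'nMito' must be >= 1")
  if (object@nContacts < 0L || object@nContacts > object@nMito)
    msg <- c(msg, "'nContacts' must lie in [0, nMito]")
  if (abs(object@frequency - object@nContacts / object@nMito) > 1e-12)
    msg <- c(msg, "'frequency' must equal nContacts / nMito")
  if (length(msg)) msg else TRUE
})
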