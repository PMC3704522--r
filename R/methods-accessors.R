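#' @rdname FluorescenceTrace-class
#' @aliases sampleTimes,FluorescenceTrace-method
setMethod("sampleTimes", "FluorescenceTrace", function(x) x@time)

#' @rdname FluorescenceTrace-class
#' @aliases intensities,FluorescenceTrace-method
setMethod("intensities", "FluorescenceTrace", function(x) x@fluorescence)

#' @rdname FluorescenceTrace-class
#' @aliases stimulusTime,FluorescenceTrace-method
setMethod("stimulusTime", "FluorescenceTrace", function(x) x@tApp)

#' @rdname FluorescenceTrace-class
#' @aliases groundTruth,FluorescenceTrace-method
setMethod("groundTruth", "FluorescenceTrace", function(x) x@groundTruth)

#' @rdname FluorescenceTrace-class
#' @aliases nSamples,FluorescenceTrace-method
setMethod("nSamples", "FluorescenceTrace", function(x) length(x@time))

#' @rdname FluorescenceTrace-class
#' @aliases samplingInterval,FluorescenceTrace-method
setMethod("samplingInterval", "FluorescenceTrace",
          function(x) mean(diff(x@time)))

setMethod("show", "FluorescenceTrace", function(object) {
  tt <- object@time
  cat("FluorescenceTrace:", length(tt), "samples,",
      sprintf("t = [%g, %g] s, dt = %g s\n", tt[1L], tt[length(tt)],
              mean(diff(tt))))
  cat("  stimulus at t =", object@tApp, "s\n")
  cat(sprintf("  fluorescence range [%.4g, %.4g] fau\n",
              min(object@fluorescence), max(object@fluorescence)))
  if (length(object@groundTruth))
    cat("  carries generator ground truth (",
        paste(names(object@groundTruth), collapse = ", "), ")\n", sep = "")
})

#' @rdname LineScanProfile-class
#' @aliases positions,LineScanProfile-method
#' @param x,object a \code{LineScanProfile}
setMethod("positions", "LineScanProfile", function(x) x@positions)

#' @rdname LineScanProfile-class
#' @aliases channel,LineScanProfile-method
#' @param which channel index, 1 or 2
setMethod("channel", "LineScanProfile", function(x, which) {
  stopifnot(which %in% c(1L, 2L))
  if (which == 1L) x@ch1 else x@ch2
})

setMethod("show", "LineScanProfile", function(object) {
  cat("LineScanProfile:", length(object@positions), "points,",
      sprintf("length %.3g um, width %d px\n",
              max(object@positions), object@widthPx))
  cat(sprintf("  endpoints (row, col): (%g, %g) -> (%g, %g)\n",
              object@endpoints[1L, 1L], object@endpoints[1L, 2L],
              object@endpoints[2L, 1L], object@endpoints[2L, 2L]))
})

#' @rdname TestResult-class
#' @aliases pValue,TestResult-method
#' @param x,object a \code{TestResult}
setMethod("pValue", "TestResult", function(x) x@pValue)

setMethod("show", "TestResult", function(object) {
  dfs <- if (length(object@df))
    paste0(", df = ", paste(format(object@df), collapse = ", ")) else ""
  stat <- if (is.na(object@statistic)) ""
          else sprintf(", statistic = %.4g", object@statistic)
  cat(sprintf("%s%s%s, p = %.4g\n", object@testName, stat, dfs,
              object@pValue))
})

#' @rdname ContactSummary-class
#' @aliases contactFrequency,ContactSummary-method
#' @param x,object a \code{ContactSummary}
setMethod("contactFrequency", "ContactSummary", function(x) x@frequency)

setMethod("show", "ContactSummary", function(object) {
  cat(sprintf(
    "ContactSummary: %d / %d mitochondria within %g nm (frequency %.3f)\n",
    object@nContacts, object@nMito, object@dMaxNm, object@frequency))
})
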