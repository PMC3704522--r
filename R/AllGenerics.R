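#' @rdname FluorescenceTrace-class
#' @param object,x a \code{FluorescenceTrace}
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname FluorescenceTrace-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname FluorescenceTrace-class
#' @export
setGeneric("stimulusTime", function(x) standardGeneric("stimulusTime"))

#' @rdname FluorescenceTrace-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname FluorescenceTrace-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname FluorescenceTrace-class
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))

#' @rdname LineScanProfile-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname LineScanProfile-class
#' @export
setGeneric("channel", function(x, which) standardGeneric("channel"))

#' @rdname TestResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname ContactSummary-class
#' @export
setGeneric("contactFrequency", function(x) standardGeneric("contactFrequency"))
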