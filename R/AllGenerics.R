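#' @include AllClasses.R
NULL

#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @export
setGeneric("traceLabel", function(x) standardGeneric("traceLabel"))

#' @export
setGeneric("traceSteps", function(x) standardGeneric("traceSteps"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))

#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))

#' @export
setGeneric("stackData", function(x) standardGeneric("stackData"))

#' @export
setGeneric("cropTime", function(x, start, end) standardGeneric("cropTime"))

#' @export
setGeneric("asTable", function(x, ...) standardGeneric("asTable"))

#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))
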