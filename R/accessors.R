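#' @include AllGenerics.R
NULL

## ---- constructors -------------------------------------------------------

#' Construct a FrameStack
#'
#' @param data numeric array indexed (frame, row, col), or a list of
#'   equally sized matrices (one per frame)
#' @param rate acquisition rate in Hz
#' @param originPath optional source path annotation
#' @return a \linkS4class{FrameStack}
#' @export
FrameStack <- function(data, rate, originPath = "") {
  if (is.list(data)) {
    dims <- unique(lapply(data, dim))
    if (length(dims) != 1L)
      stop("all frames must share one (rows, cols) shape")
    arr <- array(0, c(length(data), dims[[1]]))
    for (i in seq_along(data)) arr[i, , ] <- data[[i]]
    data <- arr
  }
  new("FrameStack", data = data, rate = as.numeric(rate),
      originPath = originPath)
}

#' Construct a RawTrace
#' @param values mean intensity per frame (a.u.)
#' @param rate sampling rate (Hz)
#' @param label source ROI label
#' @param steps provenance list (advanced use)
#' @export
RawTrace <- function(values, rate, label = "", steps = list()) {
  new("RawTrace", values = as.numeric(values), rate = as.numeric(rate),
      label = label, steps = steps)
}

#' Construct an ElectrodeTrace
#' @param values membrane potential per sample (mV)
#' @param rate sampling rate (Hz)
#' @param offset time shift in seconds relative to the optical clock
#' @param label free text
#' @param steps provenance list (advanced use)
#' @export
ElectrodeTrace <- function(values, rate, offset = 0, label = "electrode",
                           steps = list()) {
  new("ElectrodeTrace", values = as.numeric(values), rate = as.numeric(rate),
      offset = as.numeric(offset), label = label, steps = steps)
}

#' Construct a Roi
#'
#' @param kind "rectangle", "ellipse" or "polygon"
#' @param label free text
#' @param rows,cols rectangle bounds c(first, last), 1-based inclusive
#' @param center,semiAxes ellipse center c(row, col) and semi-axes
#' @param vertices polygon vertex matrix, n x 2 of (row, col)
#' @export
Roi <- function(kind, label = "", rows = NULL, cols = NULL, center = NULL,
                semiAxes = NULL, vertices = NULL) {
  geometry <- switch(kind,
    rectangle = list(rows = as.numeric(rows), cols = as.numeric(cols)),
    ellipse = list(center = as.numeric(center), semiAxes = as.numeric(semiAxes)),
    polygon = list(vertices = {
      v <- vertices
      if (!is.matrix(v)) v <- do.call(rbind, v)
      storage.mode(v) <- "double"
      v
    }),
    stop("kind must be rectangle, ellipse or polygon"))
  new("Roi", kind = kind, geometry = geometry, label = label)
}

## ---- accessors ----------------------------------------------------------

#' @describeIn traceValues per-sample values of any trace
#' @export
setMethod("traceValues", "VoltTrace", function(x) x@values)

#' @export
setMethod("sampleRate", "VoltTrace", function(x) x@rate)

#' @export
setMethod("sampleRate", "FrameStack", function(x) x@rate)

#' @export
setMethod("traceLabel", "VoltTrace", function(x) x@label)

#' @export
setMethod("traceSteps", "VoltTrace", function(x) x@steps)

#' @export
setMethod("nSamples", "VoltTrace", function(x) length(x@values))

#' @export
setMethod("duration", "VoltTrace", function(x) length(x@values) / x@rate)

#' @export
setMethod("duration", "FrameStack", function(x) dim(x@data)[1] / x@rate)

#' Time of each sample in seconds (sample 1 at t = 0)
#' @export
setMethod("timeAxis", "VoltTrace",
          function(x) (seq_along(x@values) - 1) / x@rate)

#' @export
setMethod("nFrames", "FrameStack", function(x) dim(x@data)[1])

#' @export
setMethod("frameDim", "FrameStack", function(x) dim(x@data)[2:3])

#' @export
setMethod("stackData", "FrameStack", function(x) x@data)

#' Extract one frame as a matrix
#' @param stack a FrameStack
#' @param i frame index (1-based)
#' @export
getFrame <- function(stack, i) {
  stopifnot(is(stack, "FrameStack"), i >= 1, i <= nFrames(stack))
  stack@data[i, , ]
}

#' @export
setMethod("nEvents", "SpikeSet", function(x) length(x@peakTimes))

#' @export
setMethod("nEvents", "BurstSet", function(x) nrow(x@table))

#' Spike peak times in seconds
#' @param x a SpikeSet
#' @export
peakTimes <- function(x) {
  stopifnot(is(x, "SpikeSet"))
  x@peakTimes
}

#' Spike amplitudes (peak minus threshold at the peak sample)
#' @param x a SpikeSet
#' @export
amplitudes <- function(x) {
  stopifnot(is(x, "SpikeSet"))
  x@amplitudes
}

#' Burst parameter table
#' @param x a BurstSet
#' @return data.frame with columns start, end, duration, aMax, tPeak,
#'   tauDecay, peakIndex
#' @export
burstTable <- function(x) {
  stopifnot(is(x, "BurstSet"))
  x@table
}

#' Per-frame displacement matrix of a ShiftSeries
#' @param x a ShiftSeries
#' @export
shiftMatrix <- function(x) {
  stopifnot(is(x, "ShiftSeries"))
  x@shifts
}
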