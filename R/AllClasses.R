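#' @import methods
NULL

## Central containers. All time series use sample 1 at t = 0 s; pixel
## coordinates are 1-based (row, col) with the pixel center at integer
## coordinates, as is conventional for R matrices.

.checkFiniteNumeric <- function(x, what) {
  if (!is.numeric(x)) return(sprintf("%s must be numeric", what))
  if (anyNA(x) || any(!is.finite(x))) return(sprintf("%s must be finite", what))
  NULL
}

#' FrameStack: a single-channel movie
#'
#' Holds a fluorescence movie as a 3-D numeric array indexed
#' (frame, row, col) together with its acquisition rate in Hz.
#'
#' @slot data numeric array, frames x rows x cols
#' @slot rate acquisition rate in frames per second (Hz)
#' @slot originPath path of the file the stack was read from ("" if in
#'   memory only)
#' @export
setClass("FrameStack",
  representation(data = "array", rate = "numeric", originPath = "character"),
  prototype(data = array(0, c(1, 1, 1)), rate = 1, originPath = ""))

setValidity("FrameStack", function(object) {
  msgs <- character()
  if (length(dim(object@data)) != 3L)
    msgs <- c(msgs, "data must be a 3-D array (frame, row, col)")
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msgs <- c(msgs, "rate must be a single positive number")
  m <- .checkFiniteNumeric(object@data, "intensities")
  if (!is.null(m)) msgs <- c(msgs, m)
  if (length(msgs)) msgs else TRUE
})

#' VoltTrace: virtual parent of all time-series classes
#'
#' @slot values per-sample values
#' @slot rate sampling rate (Hz)
#' @slot label free-text label (typically the source ROI)
#' @slot steps ordered provenance: one list entry per applied operation,
#'   each with elements \code{op} and \code{params}
#' @export
setClass("VoltTrace",
  representation("VIRTUAL", values = "numeric", rate = "numeric",
                 label = "character", steps = "list"))

.traceValidity <- function(object, minLength = 1L) {
  msgs <- character()
  if (length(object@values) < minLength)
    msgs <- c(msgs, sprintf("trace needs at least %d samples", minLength))
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msgs <- c(msgs, "rate must be a single positive number")
  m <- .checkFiniteNumeric(object@values, "values")
  if (!is.null(m)) msgs <- c(msgs, m)
  msgs
}

#' RawTrace: mean ROI fluorescence per frame (arbitrary units)
#' @export
setClass("RawTrace", contains = "VoltTrace")

setValidity("RawTrace", function(object) {
  msgs <- .traceValidity(object, 1L)
  if (length(msgs)) msgs else TRUE
})

#' ProcessedTrace: dF/F time series with provenance
#'
#' Values are relative fluorescence changes (F - F0)/F0, dimensionless
#' (multiply by 100 for percent; exported tables use percent).
#'
#' @slot inverted TRUE when the trace was sign-flipped, as is done for
#'   indicators that dim on depolarization
#' @export
setClass("ProcessedTrace", contains = "VoltTrace",
  representation(inverted = "logical"),
  prototype(inverted = FALSE))

setValidity("ProcessedTrace", function(object) {
  msgs <- .traceValidity(object, 2L)
  if (length(object@inverted) != 1L || is.na(object@inverted))
    msgs <- c(msgs, "inverted must be TRUE or FALSE")
  if (length(object@steps) == 0L)
    msgs <- c(msgs, "a ProcessedTrace must record at least one processing step")
  if (length(msgs)) msgs else TRUE
})

#' ElectrodeTrace: membrane potential recorded with an electrode
#'
#' @slot offset signed time shift in seconds applied when aligning to an
#'   optical trace; sample 1 of the electrode recording sits at t = offset
#'   on the optical clock
#' @export
setClass("ElectrodeTrace", contains = "VoltTrace",
  representation(offset = "numeric"),
  prototype(offset = 0))

setValidity("ElectrodeTrace", function(object) {
  msgs <- .traceValidity(object, 2L)
  if (length(object@offset) != 1L || !is.finite(object@offset))
    msgs <- c(msgs, "offset must be a single finite number")
  if (length(msgs)) msgs else TRUE
})

#' Roi: a region of interest
#'
#' Geometry by kind: \code{rectangle} uses \code{rows = c(first, last)} and
#' \code{cols = c(first, last)} (1-based, inclusive); \code{ellipse} uses
#' \code{center = c(row, col)} and \code{semiAxes = c(rowAxis, colAxis)};
#' \code{polygon} uses \code{vertices}, an n x 2 matrix of (row, col)
#' coordinates.
#'
#' @slot kind "rectangle", "ellipse" or "polygon"
#' @slot geometry named list, see above
#' @slot label free text
#' @export
setClass("Roi",
  representation(kind = "character", geometry = "list", label = "character"),
  prototype(kind = "rectangle", geometry = list(rows = c(1, 1), cols = c(1, 1)),
            label = ""))

setValidity("Roi", function(object) {
  msgs <- character()
  if (!object@kind %in% c("rectangle", "ellipse", "polygon"))
    msgs <- c(msgs, "kind must be rectangle, ellipse or polygon")
  g <- object@geometry
  if (object@kind == "rectangle" &&
      (is.null(g$rows) || is.null(g$cols) || length(g$rows) != 2 ||
       length(g$cols) != 2))
    msgs <- c(msgs, "rectangle needs rows = c(first, last), cols = c(first, last)")
  if (object@kind == "ellipse" &&
      (is.null(g$center) || is.null(g$semiAxes) || length(g$center) != 2 ||
       length(g$semiAxes) != 2 || any(g$semiAxes <= 0)))
    msgs <- c(msgs, "ellipse needs center = c(row, col) and positive semiAxes")
  if (object@kind == "polygon" &&
      (is.null(g$vertices) || !is.matrix(g$vertices) || nrow(g$vertices) < 3 ||
       ncol(g$vertices) != 2))
    msgs <- c(msgs, "polygon needs a vertices matrix with >= 3 rows of (row, col)")
  if (length(msgs)) msgs else TRUE
})

#' BaselineModel: a fitted baseline F0
#'
#' @slot kind "polynomial", "mono_exponential", "bi_exponential" or
#'   "marker_spline"
#' @slot params fitted coefficients (named list)
#' @slot fitted baseline value per sample, same length as the fitted trace
#' @slot markers sample indices (1-based) the marker_spline anchors to;
#'   empty for the other families
#' @export
setClass("BaselineModel",
  representation(kind = "character", params = "list", fitted = "numeric",
                 markers = "integer"),
  prototype(kind = "polynomial", params = list(), fitted = numeric(),
            markers = integer()))

setValidity("BaselineModel", function(object) {
  msgs <- character()
  if (!object@kind %in% c("polynomial", "mono_exponential", "bi_exponential",
                          "marker_spline"))
    msgs <- c(msgs, "unknown baseline kind")
  m <- .checkFiniteNumeric(object@fitted, "fitted baseline")
  if (!is.null(m)) msgs <- c(msgs, m)
  if (object@kind == "mono_exponential" && !is.null(object@params$b) &&
      object@params$b < 0)
    msgs <- c(msgs, "mono-exponential decay rate must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' ShiftSeries: per-frame rigid displacements
#'
#' @slot shifts n x 2 matrix of (row, col) displacements in pixels;
#'   subpixel values allowed. Displacement d means the frame content moved
#'   by +d relative to the reference image.
#' @slot reference index of the reference frame, or NA when the reference
#'   was the mean image
#' @export
setClass("ShiftSeries",
  representation(shifts = "matrix", reference = "integer"),
  prototype(shifts = matrix(0, 1, 2), reference = 1L))

setValidity("ShiftSeries", function(object) {
  msgs <- character()
  if (ncol(object@shifts) != 2L)
    msgs <- c(msgs, "shifts must have two columns (row, col)")
  m <- .checkFiniteNumeric(object@shifts, "shifts")
  if (!is.null(m)) msgs <- c(msgs, m)
  if (!is.na(object@reference)) {
    if (object@reference < 1L || object@reference > nrow(object@shifts))
      msgs <- c(msgs, "reference frame index out of range")
    else if (any(abs(object@shifts[object@reference, ]) > 1e-6))
      msgs <- c(msgs, "displacement of the reference frame must be (0, 0)")
  }
  if (length(msgs)) msgs else TRUE
})

#' DecayFit: exponential decay a * exp(-b * t)
#'
#' The decay time constant is defined as tau = 1/b; the identity holds
#' exactly in every object of this class.
#'
#' @slot a fitted amplitude (trace units), > 0
#' @slot b fitted decay rate (1/s), > 0
#' @slot tau decay time constant in seconds, identically 1/b
#' @slot rss residual sum of squares of the fit
#' @export
setClass("DecayFit",
  representation(a = "numeric", b = "numeric", tau = "numeric", rss = "numeric"),
  prototype(a = 1, b = 1, tau = 1, rss = 0))

setValidity("DecayFit", function(object) {
  msgs <- character()
  if (object@a <= 0) msgs <- c(msgs, "amplitude a must be > 0")
  if (object@b <= 0) msgs <- c(msgs, "decay rate b must be > 0")
  if (!identical(object@tau, 1 / object@b))
    msgs <- c(msgs, "tau must equal 1/b exactly")
  if (length(msgs)) msgs else TRUE
})

#' SpikeSet: detected spikes with kinetics
#'
#' @slot peakTimes spike peak times in seconds, strictly increasing
#' @slot peakIndices 1-based sample indices of the peaks
#' @slot amplitudes peak value minus the threshold at the peak sample, > 0
#' @slot tauDecay per-spike decay time constant in seconds (NA when not
#'   fitted)
#' @slot threshold the per-sample threshold curve used for detection
#' @slot rate sampling rate of the source trace (Hz)
#' @slot duration duration of the source trace (s)
#' @export
setClass("SpikeSet",
  representation(peakTimes = "numeric", peakIndices = "integer",
                 amplitudes = "numeric", tauDecay = "numeric",
                 threshold = "numeric", rate = "numeric", duration = "numeric"),
  prototype(peakTimes = numeric(), peakIndices = integer(),
            amplitudes = numeric(), tauDecay = numeric(),
            threshold = numeric(), rate = 1, duration = 0))

setValidity("SpikeSet", function(object) {
  msgs <- character()
  n <- length(object@peakTimes)
  if (length(object@peakIndices) != n || length(object@amplitudes) != n ||
      length(object@tauDecay) != n)
    msgs <- c(msgs, "peakTimes, peakIndices, amplitudes, tauDecay lengths differ")
  if (n > 1 && any(diff(object@peakTimes) <= 0))
    msgs <- c(msgs, "peak times must be strictly increasing")
  if (n > 0 && any(object@amplitudes <= 0))
    msgs <- c(msgs, "every amplitude must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' BurstSet: detected bursts with kinetic parameters
#'
#' One row of \code{table} per burst: \code{start}, \code{end},
#' \code{duration} (s), \code{aMax} (peak value), \code{tPeak} (time from
#' burst start to peak, s), \code{tauDecay} (s, NA when the decay fit
#' failed) and \code{peakIndex} (1-based sample index of the peak).
#'
#' @slot table data.frame as described above
#' @slot fits list of \linkS4class{DecayFit} (or NULL) per burst
#' @slot rate sampling rate of the source trace (Hz)
#' @export
setClass("BurstSet",
  representation(table = "data.frame", fits = "list", rate = "numeric"),
  prototype(table = data.frame(start = numeric(), end = numeric(),
                               duration = numeric(), aMax = numeric(),
                               tPeak = numeric(), tauDecay = numeric(),
                               peakIndex = integer()),
            fits = list(), rate = 1))

setValidity("BurstSet", function(object) {
  msgs <- character()
  tb <- object@table
  need <- c("start", "end", "duration", "aMax", "tPeak", "tauDecay", "peakIndex")
  if (!all(need %in% names(tb)))
    msgs <- c(msgs, paste("table must have columns", paste(need, collapse = ", ")))
  else if (nrow(tb) > 0) {
    if (any(tb$start >= tb$end)) msgs <- c(msgs, "each burst needs start < end")
    if (any(tb$tPeak < 0 | tb$tPeak > tb$duration + 1e-12))
      msgs <- c(msgs, "tPeak must lie within [0, duration]")
  }
  if (length(object@fits) != nrow(tb))
    msgs <- c(msgs, "one fit entry (possibly NULL) per burst required")
  if (length(msgs)) msgs else TRUE
})

#' EventShape: peak-aligned average event waveform
#'
#' @slot waveform pointwise mean over the aligned event windows
#' @slot sd pointwise standard deviation (0 when a single event)
#' @slot nEvents number of events averaged
#' @slot nExcluded events dropped because their window left the trace
#' @slot pre,post window extent before/after the peak (s)
#' @slot rate sampling rate (Hz)
#' @export
setClass("EventShape",
  representation(waveform = "numeric", sd = "numeric", nEvents = "integer",
                 nExcluded = "integer", pre = "numeric", post = "numeric",
                 rate = "numeric"),
  prototype(waveform = numeric(), sd = numeric(), nEvents = 0L,
            nExcluded = 0L, pre = 0, post = 0, rate = 1))

setValidity("EventShape", function(object) {
  msgs <- character()
  if (object@nEvents < 1L) msgs <- c(msgs, "at least one event required")
  expected <- round((object@pre + object@post) * object@rate) + 1
  if (length(object@waveform) != expected)
    msgs <- c(msgs, "waveform length must be round((pre+post)*rate) + 1")
  if (length(object@sd) != length(object@waveform))
    msgs <- c(msgs, "sd must match waveform length")
  if (length(msgs)) msgs else TRUE
})

#' PowerSpectrum: one-sided power spectral density
#'
#' Density normalization: the integral of \code{power} over \code{freqs}
#' approximates the variance of the (mean-removed, tapered) trace.
#'
#' @slot freqs frequency grid in Hz, strictly increasing, spanning
#'   [0, rate/2]
#' @slot power spectral density (trace units squared per Hz), >= 0
#' @slot method "periodogram" or "averaged_segment"
#' @slot segmentLength segment length in seconds (averaged_segment only,
#'   NA otherwise)
#' @export
setClass("PowerSpectrum",
  representation(freqs = "numeric", power = "numeric", method = "character",
                 segmentLength = "numeric"),
  prototype(freqs = numeric(), power = numeric(), method = "periodogram",
            segmentLength = NA_real_))

setValidity("PowerSpectrum", function(object) {
  msgs <- character()
  if (length(object@freqs) != length(object@power))
    msgs <- c(msgs, "freqs and power lengths differ")
  if (length(object@freqs) > 1 && any(diff(object@freqs) <= 0))
    msgs <- c(msgs, "freqs must be strictly increasing")
  if (any(object@power < 0)) msgs <- c(msgs, "power must be >= 0")
  if (!object@method %in% c("periodogram", "averaged_segment"))
    msgs <- c(msgs, "unknown spectral method")
  if (length(msgs)) msgs else TRUE
})

#' Correlogram: lag-domain summary of two signals or spike trains
#'
#' Sign convention: a positive lag means the second argument lags (follows)
#' the first.
#'
#' @slot lags lags in seconds, strictly increasing and symmetric about 0
#' @slot values Pearson correlation per lag (amplitude/instantaneous kinds,
#'   in [-1, 1]) or normalized pair rate per bin (spike kind)
#' @slot counts raw pair counts per bin (spike kind only, empty otherwise)
#' @slot kind "amplitude", "spike" or "instantaneous"
#' @slot band optional band-pass edges c(low, high) in Hz applied before
#'   correlation (empty when none)
#' @export
setClass("Correlogram",
  representation(lags = "numeric", values = "numeric", counts = "numeric",
                 kind = "character", band = "numeric"),
  prototype(lags = numeric(), values = numeric(), counts = numeric(),
            kind = "amplitude", band = numeric()))

setValidity("Correlogram", function(object) {
  msgs <- character()
  if (length(object@lags) != length(object@values))
    msgs <- c(msgs, "lags and values lengths differ")
  if (length(object@lags) > 1) {
    if (any(diff(object@lags) <= 0))
      msgs <- c(msgs, "lags must be strictly increasing")
    if (max(abs(object@lags + rev(object@lags))) > 1e-9)
      msgs <- c(msgs, "lags must be symmetric about zero")
  }
  if (!object@kind %in% c("amplitude", "spike", "instantaneous"))
    msgs <- c(msgs, "unknown correlogram kind")
  if (object@kind %in% c("amplitude", "instantaneous") &&
      length(object@values) && max(abs(object@values)) > 1 + 1e-9)
    msgs <- c(msgs, "correlation values must lie in [-1, 1]")
  if (length(msgs)) msgs else TRUE
})

#' SynthSpec: recipe for a synthetic voltage-imaging trace
#'
#' @slot duration recording length (s)
#' @slot rate sampling rate (Hz)
#' @slot components list of signal components built with
#'   \code{\link{oscillation}}, \code{\link{spikeComponent}} or
#'   \code{\link{burstComponent}}
#' @slot bleach c(a, b) of the photobleaching baseline a * exp(-b * t)
#' @slot noiseSd additive Gaussian noise SD (trace units)
#' @slot invert emulate an indicator that dims on depolarization
#' @slot seed RNG seed; equal specs give bit-identical traces
#' @export
setClass("SynthSpec",
  representation(duration = "numeric", rate = "numeric", components = "list",
                 bleach = "numeric", noiseSd = "numeric", invert = "logical",
                 seed = "integer"),
  prototype(duration = 10, rate = 100, components = list(),
            bleach = c(a = 100, b = 0), noiseSd = 0, invert = FALSE,
            seed = 1L))

setValidity("SynthSpec", function(object) {
  msgs <- character()
  if (object@duration * object@rate < 16)
    msgs <- c(msgs, "duration * rate must be >= 16 samples")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (length(object@bleach) != 2 || object@bleach[1] <= 0 || object@bleach[2] < 0)
    msgs <- c(msgs, "bleach must be c(a > 0, b >= 0)")
  if (length(msgs)) msgs else TRUE
})
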