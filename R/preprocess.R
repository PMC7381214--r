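#' @include roi.R
NULL

## ---- cropping -----------------------------------------------------------

#' Temporal crop
#'
#' Keeps samples (or frames) with start <= t < end and restarts the clock
#' at the new first sample (t = 0).
#'
#' @param x a trace or a \linkS4class{FrameStack}
#' @param start,end window in seconds, 0 <= start < end <= duration
#' @return an object of the same class
#' @export
setMethod("cropTime", "VoltTrace", function(x, start, end) {
  idx <- .cropIndices(length(x@values), x@rate, start, end)
  .withValues(x, x@values[idx],
              steps = .addStep(x@steps, "crop",
                               list(start = start, end = end)))
})

#' @rdname cropTime-VoltTrace-method
#' @export
setMethod("cropTime", "FrameStack", function(x, start, end) {
  idx <- .cropIndices(nFrames(x), x@rate, start, end)
  initialize(x, data = x@data[idx, , , drop = FALSE])
})

.cropIndices <- function(n, rate, start, end) {
  dur <- n / rate
  if (!(start >= 0 && start < end && end <= dur + 1e-9))
    stop("crop window must satisfy 0 <= start < end <= duration")
  ## half-open [start, end): samples with t = (i-1)/rate in the window
  i0 <- ceiling(start * rate - 1e-9) + 1
  i1 <- ceiling(end * rate - 1e-9)
  if (i1 < i0) stop("crop window contains no samples")
  i0:min(i1, n)
}

## ---- background ---------------------------------------------------------

#' Subtract a (zero-centered) background trace
#'
#' The background is centered on its own mean before scaling and
#' subtraction, so the mean level of the signal is preserved:
#' out[i] = signal[i] - scale * (background[i] - mean(background)).
#'
#' @param signal,background \linkS4class{RawTrace}s of equal length and
#'   rate (the background typically from \code{\link{perisomaticAnnulus}})
#' @param scale fraction in [0, 1] of the background fluctuation to remove
#' @return a \linkS4class{RawTrace}
#' @export
subtractBackground <- function(signal, background, scale = 1) {
  stopifnot(is(signal, "RawTrace"), is(background, "RawTrace"),
            scale >= 0, scale <= 1)
  if (length(signal@values) != length(background@values))
    stop("signal and background lengths differ")
  if (abs(signal@rate - background@rate) > 1e-9)
    stop("signal and background rates differ")
  bg <- background@values - mean(background@values)
  .withValues(signal, signal@values - scale * bg,
              steps = .addStep(signal@steps, "background",
                               list(scale = scale,
                                    background = background@label)))
}

## ---- baseline -----------------------------------------------------------

#' Fit a baseline model to a raw trace
#'
#' Families: \code{polynomial} (least squares of given degree),
#' \code{mono_exponential} a*exp(-b*t) + c and \code{bi_exponential}
#' a1*exp(-b1*t) + a2*exp(-b2*t) + c (Levenberg-Marquardt, for
#' photobleaching and photoisomerization drifts), and \code{marker_spline},
#' a monotone-segment cubic through user-set markers, anchored at the
#' 5-sample local median of the trace around each marker (constant
#' extension beyond the outermost markers).
#'
#' @param trace a \linkS4class{RawTrace}
#' @param kind baseline family, see above
#' @param degree polynomial degree (polynomial only)
#' @param markers 1-based sample indices (marker_spline only, >= 2)
#' @return a \linkS4class{BaselineModel}
#' @export
fitBaseline <- function(trace, kind = c("polynomial", "mono_exponential",
                                        "bi_exponential", "marker_spline"),
                        degree = 1, markers = NULL) {
  stopifnot(is(trace, "VoltTrace"))
  kind <- match.arg(kind)
  y <- trace@values
  n <- length(y)
  t <- (seq_len(n) - 1) / trace@rate
  nFree <- switch(kind, polynomial = degree + 1, mono_exponential = 3,
                  bi_exponential = 5, marker_spline = length(markers))
  if (kind != "marker_spline" && n < nFree + 2)
    stop("too few samples for this baseline family")

  if (kind == "polynomial") {
    fit <- if (degree == 0) stats::lm(y ~ 1)
           else stats::lm(y ~ stats::poly(t, degree))
    model <- new("BaselineModel", kind = kind,
                 params = list(degree = degree,
                               coefficients = unname(stats::coef(fit))),
                 fitted = as.numeric(stats::fitted(fit)), markers = integer())
  } else if (kind == "mono_exponential") {
    model <- .fitMonoExp(y, t)
  } else if (kind == "bi_exponential") {
    model <- .fitBiExp(y, t)
  } else {
    if (is.null(markers) || length(markers) < 2)
      stop("marker_spline needs at least 2 markers")
    markers <- sort(unique(as.integer(markers)))
    if (any(markers < 1 | markers > n)) stop("markers out of range")
    anchors <- vapply(markers, function(m) {
      stats::median(y[max(1, m - 2):min(n, m + 2)])
    }, numeric(1))
    sf <- stats::splinefun(t[markers], anchors, method = "monoH.FC")
    fitted <- sf(pmin(pmax(t, t[markers[1]]), t[markers[length(markers)]]))
    model <- new("BaselineModel", kind = kind,
                 params = list(anchors = anchors),
                 fitted = fitted, markers = markers)
  }

  ## sanity: a least-squares family must beat the constant-mean baseline
  if (kind != "marker_spline") {
    rss <- sum((y - model@fitted)^2)
    rss0 <- sum((y - mean(y))^2)
    if (rss > rss0 * (1 + 1e-9) + 1e-12 * max(1, mean(y^2)))
      stop("baseline fit is worse than a constant mean; fit is degenerate")
  }
  model
}

.fitMonoExp <- function(y, t) {
  n <- length(y)
  c0 <- min(y) - 0.05 * max(diff(range(y)), 1e-12)
  a0 <- max(y[1] - c0, 1e-12)
  tail0 <- max(mean(y[max(1, n - 4):n]) - c0, a0 * 1e-6)
  b0 <- max(log(a0 / tail0), 0.01) / max(t[n], 1e-12)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-b * t) + c,
                      start = list(a = a0, b = b0, c = c0),
                      lower = c(a = -Inf, b = 0, c = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("mono-exponential baseline fit failed: ",
                             conditionMessage(e)))
  p <- as.list(stats::coef(fit))
  new("BaselineModel", kind = "mono_exponential", params = p,
      fitted = as.numeric(stats::fitted(fit)), markers = integer())
}

.fitBiExp <- function(y, t) {
  c0 <- min(y) - 0.05 * max(diff(range(y)), 1e-12)
  a0 <- max(y[1] - c0, 1e-12)
  dur <- max(t[length(t)], 1e-12)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a1 * exp(-b1 * t) + a2 * exp(-b2 * t) + c,
                      start = list(a1 = 0.7 * a0, b1 = 5 / dur,
                                   a2 = 0.3 * a0, b2 = 0.5 / dur, c = c0),
                      lower = c(a1 = -Inf, b1 = 0, a2 = -Inf, b2 = 0, c = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("bi-exponential baseline fit failed: ",
                             conditionMessage(e)))
  p <- as.list(stats::coef(fit))
  new("BaselineModel", kind = "bi_exponential", params = p,
      fitted = as.numeric(stats::fitted(fit)), markers = integer())
}

## ---- dF/F ---------------------------------------------------------------

#' Compute dF/F against a fitted baseline
#'
#' dF/F[i] = (F[i] - F0[i]) / F0[i], with F0 the fitted baseline. With
#' \code{invert = TRUE} the result is multiplied by -1, as appropriate for
#' indicators whose fluorescence decreases on depolarization (e.g.
#' ArcLight).
#'
#' @param trace the \linkS4class{RawTrace} the baseline was fitted on
#' @param baseline a \linkS4class{BaselineModel}
#' @param invert sign-flip the result
#' @return a \linkS4class{ProcessedTrace}
#' @export
computeDFF <- function(trace, baseline, invert = FALSE) {
  stopifnot(is(trace, "RawTrace"), is(baseline, "BaselineModel"))
  F0 <- baseline@fitted
  if (length(F0) != length(trace@values))
    stop("baseline was not fitted on this trace (length mismatch)")
  if (any(F0 <= 0))
    stop("baseline has nonpositive samples; dF/F undefined")
  steps <- .addStep(trace@steps, "baseline",
                    list(kind = baseline@kind))
  steps <- .addStep(steps, "dff", list(invert = invert))
  v <- (trace@values - F0) / F0
  if (invert) v <- -v
  new("ProcessedTrace", values = v, rate = trace@rate, label = trace@label,
      steps = steps, inverted = invert)
}

#' Sign-flip a processed trace
#'
#' Applying it twice restores the original values.
#' @param trace a \linkS4class{ProcessedTrace}
#' @export
invertTrace <- function(trace) {
  stopifnot(is(trace, "ProcessedTrace"))
  initialize(trace, values = -trace@values, inverted = !trace@inverted,
             steps = .addStep(trace@steps, "dff", list(invert = TRUE)))
}

## ---- filtering ----------------------------------------------------------

#' Filter or smooth a processed trace
#'
#' All filters preserve length and rate and are zero-phase: band filters
#' (Butterworth order 3) are applied forward-backward, Savitzky-Golay and
#' moving-average kernels are symmetric. Types and their parameters:
#' \describe{
#'   \item{savitzky_golay}{\code{window} (odd sample count),
#'     \code{polyorder} < window}
#'   \item{moving_average}{\code{window} (samples), \code{taper} "flat" or
#'     "hann"; edges use the truncated, renormalized window}
#'   \item{band_pass}{\code{low}, \code{high} in Hz,
#'     0 <= low < high <= rate/2}
#'   \item{low_pass, high_pass}{\code{cutoff} in Hz}
#' }
#'
#' @param trace a \linkS4class{ProcessedTrace} (or any trace for smoothing
#'   outside the dF/F pipeline)
#' @param type filter type, see above
#' @param window,polyorder,taper,low,high,cutoff type-specific parameters
#' @return same class as \code{trace}
#' @export
applyFilter <- function(trace, type = c("savitzky_golay", "moving_average",
                                        "band_pass", "low_pass", "high_pass"),
                        window = NULL, polyorder = 2, taper = c("flat", "hann"),
                        low = NULL, high = NULL, cutoff = NULL) {
  stopifnot(is(trace, "VoltTrace"))
  type <- match.arg(type)
  x <- trace@values
  rate <- trace@rate
  nyq <- rate / 2
  out <- switch(type,
    savitzky_golay = {
      if (is.null(window) || window %% 2 != 1 || window < 3)
        stop("savitzky_golay needs an odd window >= 3 (samples)")
      if (polyorder >= window) stop("polyorder must be < window")
      params <- list(window = window, polyorder = polyorder)
      signal::sgolayfilt(x, p = polyorder, n = window)
    },
    moving_average = {
      taper <- match.arg(taper)
      if (is.null(window) || window < 1) stop("moving_average needs window >= 1")
      params <- list(window = window, taper = taper)
      .movingAverage(x, window, taper)
    },
    band_pass = {
      if (is.null(low) || is.null(high) || low < 0 || low >= high || high > nyq)
        stop("band_pass needs 0 <= low < high <= rate/2")
      params <- list(low = low, high = high)
      .zeroPhaseButter(x, rate, c(low, high), "pass")
    },
    low_pass = {
      if (is.null(cutoff) || cutoff <= 0 || cutoff > nyq)
        stop("low_pass needs 0 < cutoff <= rate/2")
      params <- list(cutoff = cutoff)
      .zeroPhaseButter(x, rate, cutoff, "low")
    },
    high_pass = {
      if (is.null(cutoff) || cutoff <= 0 || cutoff > nyq)
        stop("high_pass needs 0 < cutoff <= rate/2")
      params <- list(cutoff = cutoff)
      .zeroPhaseButter(x, rate, cutoff, "high")
    })
  if (any(!is.finite(out))) stop("filter produced non-finite values")
  .withValues(trace, out,
              steps = .addStep(trace@steps, "filter",
                               c(list(type = type), params)))
}

## Butterworth order 3, forward-backward (zero phase). Corner frequencies
## at the Nyquist limit are nudged just below it to keep the design stable.
.zeroPhaseButter <- function(x, rate, corners, type) {
  w <- pmin(corners / (rate / 2), 0.999)
  w <- pmax(w, 1e-6)
  bf <- signal::butter(3, w, type = type)
  as.numeric(signal::filtfilt(bf, x))
}

## Centered moving average; edge samples use the truncated window,
## renormalized, so constants are preserved everywhere.
.movingAverage <- function(x, window, taper = "flat") {
  w <- if (taper == "hann" && window > 2) {
    0.5 * (1 - cos(2 * pi * (0:(window - 1)) / (window - 1)))
  } else rep(1, window)
  if (sum(w) == 0) w <- rep(1, window)
  n <- length(x)
  num <- stats::convolve(c(rep(0, window), x, rep(0, window)), rev(w),
                         type = "open")
  den <- stats::convolve(c(rep(0, window), rep(1, n), rep(0, window)), rev(w),
                         type = "open")
  ## center the full convolution on the input grid
  half <- floor(window / 2)
  idx <- (window + half + 1):(window + half + n)
  num[idx] / den[idx]
}

## ---- resampling ---------------------------------------------------------

#' Resample a trace to a new rate
#'
#' Values are interpolated at t = k / newRate, k = 0, 1, ..., within the
#' span of the original samples; the duration is preserved to within one
#' sample period.
#'
#' @param x any trace
#' @param newRate target rate in Hz
#' @param method "linear" or "cubic" (spline) interpolation
#' @return same class as \code{x} with rate \code{newRate}
#' @export
resampleTrace <- function(x, newRate, method = c("linear", "cubic")) {
  stopifnot(is(x, "VoltTrace"), newRate > 0)
  method <- match.arg(method)
  n <- length(x@values)
  tOld <- (seq_len(n) - 1) / x@rate
  m <- floor(tOld[n] * newRate + 1e-9) + 1
  if (m < 2) stop("new rate yields fewer than 2 samples")
  tNew <- (seq_len(m) - 1) / newRate
  v <- if (method == "linear") {
    stats::approx(tOld, x@values, xout = tNew)$y
  } else {
    stats::splinefun(tOld, x@values, method = "fmm")(tNew)
  }
  .withValues(x, v, rate = newRate,
              steps = .addStep(x@steps, "resample",
                               list(rate = newRate, method = method)))
}

#' Suggested resampling frequency
#'
#' Two rules: to resolve event intervals the rate should be twice the
#' signal frequency (Nyquist); to resolve event shape it should be at
#' least 10 times faster than the shortest event. The combined mode takes
#' the maximum of both.
#'
#' @param mode "event_intervals", "event_shape" or "combined"
#' @param signalFreq dominant signal frequency in Hz (interval modes)
#' @param shortestEvent shortest event duration in seconds (shape modes)
#' @return suggested rate in Hz
#' @export
suggestResampling <- function(mode = c("event_intervals", "event_shape",
                                       "combined"),
                              signalFreq = NULL, shortestEvent = NULL) {
  mode <- match.arg(mode)
  needFreq <- mode %in% c("event_intervals", "combined")
  needEvent <- mode %in% c("event_shape", "combined")
  if (needFreq && (is.null(signalFreq) || signalFreq <= 0))
    stop("signalFreq must be given and > 0 for this mode")
  if (needEvent && (is.null(shortestEvent) || shortestEvent <= 0))
    stop("shortestEvent must be given and > 0 for this mode")
  switch(mode,
         event_intervals = 2 * signalFreq,
         event_shape = 10 / shortestEvent,
         combined = max(2 * signalFreq, 10 / shortestEvent))
}

## ---- modality alignment -------------------------------------------------

#' Shift an electrode trace relative to an optical trace
#'
#' Sets the electrode offset so that its sample 1 sits at t = offset on
#' the optical clock, and records the resulting overlap window. Samples
#' outside the overlap are dropped from joint analyses (see
#' \code{\link{extractOverlap}}).
#'
#' @param optical a \linkS4class{ProcessedTrace}
#' @param electrode an \linkS4class{ElectrodeTrace}
#' @param offset signed shift in seconds; |offset| must be smaller than
#'   the electrode duration
#' @return the shifted \linkS4class{ElectrodeTrace}
#' @export
alignOffset <- function(optical, electrode, offset) {
  stopifnot(is(optical, "VoltTrace"), is(electrode, "ElectrodeTrace"))
  if (abs(offset) >= duration(electrode))
    stop("|offset| must be smaller than the electrode trace duration")
  shifted <- initialize(electrode, offset = offset)
  ov <- overlapWindow(optical, shifted)
  if (ov[2] - ov[1] <= 0) stop("no overlap between the traces at this offset")
  initialize(shifted,
             steps = .addStep(electrode@steps, "align",
                              list(offset = offset,
                                   overlap = as.numeric(ov))))
}

#' Overlap window of an optical and a (shifted) electrode trace
#'
#' @param optical any trace on the optical clock
#' @param electrode an \linkS4class{ElectrodeTrace} (its offset is honored)
#' @return c(start, end) in seconds on the optical clock
#' @export
overlapWindow <- function(optical, electrode) {
  c(max(0, electrode@offset),
    min(duration(optical), electrode@offset + duration(electrode)))
}

#' Joint samples of an aligned optical/electrode pair
#'
#' Restricts both traces to their overlap window and interpolates the
#' electrode trace (linearly) onto the optical sample grid, unifying the
#' rates for joint analyses such as cross-correlation.
#'
#' @param optical a \linkS4class{ProcessedTrace}
#' @param electrode an aligned \linkS4class{ElectrodeTrace}
#' @return list with elements \code{optical} and \code{electrode}, traces
#'   of equal rate and length
#' @export
extractOverlap <- function(optical, electrode) {
  ov <- overlapWindow(optical, electrode)
  if (ov[2] - ov[1] <= 0) stop("traces do not overlap")
  tOpt <- timeAxis(optical)
  keep <- tOpt >= ov[1] - 1e-12 & tOpt < ov[2] - 1e-12
  if (sum(keep) < 2) stop("overlap contains fewer than 2 optical samples")
  tJoint <- tOpt[keep]
  eVals <- stats::approx(timeAxis(electrode) + electrode@offset,
                         electrode@values, xout = tJoint, rule = 2)$y
  list(optical = .withValues(optical, optical@values[keep]),
       electrode = ElectrodeTrace(eVals, rate = optical@rate,
                                  offset = tJoint[1],
                                  label = electrode@label))
}
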