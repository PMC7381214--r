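#' @include register.R
NULL

## Polarity: hyperpolarization events are detected on the sign-flipped
## trace ("negative" polarity). The threshold curve supplied to the
## detectors is interpreted on that flipped scale.
.orient <- function(values, polarity) {
  if (polarity == "negative") -values else values
}

#' Per-sample detection threshold
#'
#' \code{static} is a constant line at \code{level}. \code{dynamic} is a
#' centered moving average of the trace over \code{window} seconds plus
#' \code{k} times the noise SD, where the noise SD is estimated from the
#' first difference of the trace as sd(diff(x)) / sqrt(2) — robust to the
#' slow oscillations the moving average tracks.
#'
#' @param trace any trace
#' @param mode "static" or "dynamic"
#' @param level static threshold level
#' @param window dynamic: averaging window in seconds (>= 3 samples)
#' @param k dynamic: noise-SD multiplier
#' @return numeric per-sample threshold curve
#' @export
makeThreshold <- function(trace, mode = c("static", "dynamic"), level = NULL,
                          window = 1, k = 3) {
  stopifnot(is(trace, "VoltTrace"))
  mode <- match.arg(mode)
  n <- length(trace@values)
  if (mode == "static") {
    if (is.null(level) || !is.finite(level)) stop("static mode needs a finite level")
    return(rep(as.numeric(level), n))
  }
  if (window <= 0 || k <= 0) stop("dynamic mode needs window > 0 and k > 0")
  w <- round(window * trace@rate)
  if (w < 3) stop("dynamic threshold window shorter than 3 samples")
  sigma <- stats::sd(diff(trace@values)) / sqrt(2)
  .movingAverage(trace@values, w, "flat") + k * sigma
}

#' Detect spikes with a threshold curve
#'
#' Spikes are the local maxima of supra-threshold runs: each maximal run
#' of samples strictly above the threshold yields exactly one spike at its
#' maximum (earliest index on ties). Peaks closer together than the
#' refractory period keep the larger amplitude. Amplitude is the peak
#' value minus the threshold at the peak sample.
#'
#' @param trace a \linkS4class{ProcessedTrace} or
#'   \linkS4class{ElectrodeTrace}
#' @param threshold per-sample threshold curve (same length as the trace),
#'   e.g. from \code{\link{makeThreshold}}
#' @param refractory minimum peak separation in seconds (0 disables)
#' @param polarity "positive", or "negative" to detect hyperpolarization
#'   events on the sign-flipped trace
#' @param fitTau also fit a per-spike exponential decay on the samples
#'   from the peak to the end of its supra-threshold run
#' @return a \linkS4class{SpikeSet} (possibly empty)
#' @export
detectSpikes <- function(trace, threshold, refractory = 0,
                         polarity = c("positive", "negative"),
                         fitTau = FALSE) {
  stopifnot(is(trace, "VoltTrace"))
  polarity <- match.arg(polarity)
  v <- .orient(trace@values, polarity)
  n <- length(v)
  if (length(threshold) != n)
    stop("threshold curve length must match the trace")
  above <- v > threshold
  runs <- .runsOf(above)
  peaks <- integer(0)
  for (r in seq_len(nrow(runs))) {
    seg <- runs[r, 1]:runs[r, 2]
    peaks <- c(peaks, seg[which.max(v[seg])])
  }
  ## refractory: keep the larger amplitude of peaks closer than refractory
  amp <- v[peaks] - threshold[peaks]
  if (refractory > 0 && length(peaks) > 1) {
    minGap <- refractory * trace@rate
    keep <- integer(0)
    for (p in seq_along(peaks)) {
      if (length(keep) && (peaks[p] - peaks[keep[length(keep)]]) < minGap) {
        if (amp[p] > amp[keep[length(keep)]]) keep[length(keep)] <- p
      } else keep <- c(keep, p)
    }
    peaks <- peaks[keep]; amp <- amp[keep]
  }
  tau <- rep(NA_real_, length(peaks))
  if (fitTau && length(peaks)) {
    runEnd <- vapply(peaks, function(p) {
      r <- which(runs[, 1] <= p & runs[, 2] >= p)
      runs[r, 2]
    }, numeric(1))
    for (p in seq_along(peaks)) {
      seg <- v[peaks[p]:runEnd[p]]
      if (length(seg) >= 4 && seg[1] > 0) {
        fit <- tryCatch(fitDecay(seg, trace@rate), error = function(e) NULL)
        if (!is.null(fit)) tau[p] <- fit@tau
      }
    }
  }
  new("SpikeSet", peakTimes = (peaks - 1) / trace@rate,
      peakIndices = as.integer(peaks), amplitudes = amp, tauDecay = tau,
      threshold = threshold, rate = trace@rate, duration = n / trace@rate)
}

## start/end indices of TRUE runs as a 2-column matrix
.runsOf <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(starts, ends)[r$values, , drop = FALSE]
}

#' Detect bursts with a threshold curve
#'
#' A burst starts at an upward threshold crossing and ends when the trace
#' falls below threshold + endFraction * (A_max - threshold) — with A_max
#' the largest in-burst value so far — and stays below for at least 3
#' samples (or the trace ends). Bursts shorter than \code{minDuration}
#' are discarded. Per burst, A_max, t_peak (burst start to peak) and
#' tau_decay (exponential fit from the peak to the burst end, see
#' \code{\link{fitDecay}}) are quantified.
#'
#' @param trace a \linkS4class{ProcessedTrace} or
#'   \linkS4class{ElectrodeTrace}
#' @param threshold per-sample threshold curve
#' @param minDuration minimum burst duration in seconds
#' @param endFraction fractional-return criterion in (0, 1]
#' @param polarity "positive" or "negative" (sign-flipped trace)
#' @return a \linkS4class{BurstSet} (possibly empty)
#' @export
detectBursts <- function(trace, threshold, minDuration = 0,
                         endFraction = 0.5,
                         polarity = c("positive", "negative")) {
  stopifnot(is(trace, "VoltTrace"))
  polarity <- match.arg(polarity)
  if (!(endFraction > 0 && endFraction <= 1))
    stop("endFraction must lie in (0, 1]")
  v <- .orient(trace@values, polarity)
  n <- length(v)
  if (length(threshold) != n)
    stop("threshold curve length must match the trace")
  rate <- trace@rate
  rows <- list(); fits <- list()
  i <- 1L
  while (i <= n) {
    ## next upward crossing
    while (i <= n && !(v[i] > threshold[i] && (i == 1L || v[i - 1] <= threshold[i - 1])))
      i <- i + 1L
    if (i > n) break
    start <- i
    aMax <- v[i]; peak <- i
    j <- i
    endIdx <- n
    below <- 0L
    while (j <= n) {
      if (v[j] > aMax) { aMax <- v[j]; peak <- j }
      lvl <- threshold[j] + endFraction * (aMax - threshold[j])
      if (j > peak && v[j] < lvl) {
        below <- below + 1L
        if (below == 1L) endIdx <- j
        if (below >= 3L) break
      } else {
        below <- 0L
        endIdx <- n
      }
      j <- j + 1L
    }
    if (below < 3L) endIdx <- n
    dur <- (endIdx - start) / rate
    if (dur + 1e-12 >= minDuration) {
      seg <- v[peak:endIdx]
      fit <- NULL
      if (length(seg) >= 4 && seg[1] > 0)
        fit <- tryCatch(fitDecay(seg, rate), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        start = (start - 1) / rate, end = (endIdx - 1) / rate,
        duration = dur, aMax = aMax, tPeak = (peak - start) / rate,
        tauDecay = if (is.null(fit)) NA_real_ else fit@tau,
        peakIndex = as.integer(peak))
      fits[[length(fits) + 1L]] <- fit
    }
    ## resume after the burst, once the trace has returned below threshold
    i <- max(endIdx, start) + 1L
    while (i <= n && v[i] > threshold[i]) i <- i + 1L
  }
  tb <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = numeric(), end = numeric(), duration = numeric(),
               aMax = numeric(), tPeak = numeric(), tauDecay = numeric(),
               peakIndex = integer())
  new("BurstSet", table = tb, fits = fits, rate = rate)
}

#' Fit an exponential decay a * exp(-b * t)
#'
#' Nonlinear least squares (Levenberg-Marquardt) on the segment after a
#' peak, initialized at a0 = first sample and b0 = 1 / segment duration.
#' The decay time constant is tau = 1/b, exactly.
#'
#' @param segment trace values from the peak onward
#' @param rate sampling rate in Hz
#' @return a \linkS4class{DecayFit}
#' @export
fitDecay <- function(segment, rate) {
  y <- as.numeric(segment)
  if (length(y) < 4) stop("decay fit needs at least 4 samples")
  if (y[1] <= 0) stop("decay fit needs a positive first sample")
  t <- (seq_along(y) - 1) / rate
  dur <- t[length(t)]
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-b * t),
                      start = list(a = y[1], b = 1 / dur),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ptol = 1e-8, ftol = 1e-14)),
    error = function(e) stop("decay fit did not converge: ",
                             conditionMessage(e)))
  p <- stats::coef(fit)
  if (p[["b"]] <= 0) stop("decay fit returned a nonpositive decay rate")
  if (p[["a"]] <= 0) stop("decay fit returned a nonpositive amplitude")
  new("DecayFit", a = p[["a"]], b = p[["b"]], tau = 1 / p[["b"]],
      rss = sum(stats::resid(fit)^2))
}

#' Peak-aligned average event waveform
#'
#' Windows of [-pre, +post] seconds around each event peak are aligned on
#' the peak sample and averaged pointwise; events whose window would leave
#' the trace are excluded (and counted). The per-sample SD across events
#' is reported alongside the mean.
#'
#' @param trace the trace the events were detected on
#' @param events a \linkS4class{SpikeSet} or \linkS4class{BurstSet}
#' @param pre,post window extent before/after the peak, in seconds
#' @return an \linkS4class{EventShape}
#' @export
eventShape <- function(trace, events, pre, post) {
  stopifnot(is(trace, "VoltTrace"), pre >= 0, post >= 0)
  peaks <- if (is(events, "SpikeSet")) events@peakIndices
           else if (is(events, "BurstSet")) events@table$peakIndex
           else stop("events must be a SpikeSet or BurstSet")
  if (length(peaks) == 0) stop("no events to average")
  rate <- trace@rate
  npre <- round(pre * rate); npost <- round(post * rate)
  n <- length(trace@values)
  ok <- peaks - npre >= 1 & peaks + npost <= n
  if (!any(ok)) stop("no event window lies fully inside the trace")
  windows <- vapply(peaks[ok], function(p) {
    trace@values[(p - npre):(p + npost)]
  }, numeric(npre + npost + 1))
  windows <- matrix(windows, nrow = npre + npost + 1)
  m <- rowMeans(windows)
  s <- if (ncol(windows) > 1) apply(windows, 1, stats::sd) else
    rep(0, length(m))
  new("EventShape", waveform = m, sd = s, nEvents = as.integer(sum(ok)),
      nExcluded = as.integer(sum(!ok)), pre = npre / rate, post = npost / rate,
      rate = rate)
}
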