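#' @include spectral.R
NULL

## Per-lag Pearson correlation over the truncated overlap. Positive lag:
## the second signal lags (follows) the first. This bounded per-lag
## normalization (rather than an FFT covariance estimate) keeps every
## value in [-1, 1].
.pearsonXcorr <- function(a, b, maxLagSamples) {
  n <- length(a)
  L <- maxLagSamples
  if (n - L < 3) stop("traces too short for the requested max lag")
  vals <- vapply(-L:L, function(l) {
    if (l >= 0) { x <- a[1:(n - l)]; y <- b[(1 + l):n] }
    else { x <- a[(1 - l):n]; y <- b[1:(n + l)] }
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("zero-variance overlap window; correlation undefined")
    stats::cor(x, y)
  }, numeric(1))
  vals
}

#' Amplitude cross-correlation of two dF/F traces
#'
#' The value at lag l is the Pearson correlation of a(t) with b(t + l)
#' over the overlapping samples; a positive lag means b follows a. An
#' optional band-pass (applied to both traces first) restricts the
#' comparison to a frequency range of interest.
#'
#' @param a,b traces of equal rate (resample first otherwise)
#' @param maxLag largest lag in seconds; the traces must overlap by at
#'   least twice this
#' @param band optional c(low, high) band-pass edges in Hz
#' @return a \linkS4class{Correlogram} of kind "amplitude"
#' @export
amplitudeXcorr <- function(a, b, maxLag, band = NULL) {
  stopifnot(is(a, "VoltTrace"), is(b, "VoltTrace"))
  if (abs(a@rate - b@rate) > 1e-9)
    stop("rates differ; resample one trace first")
  va <- a@values; vb <- b@values
  n <- min(length(va), length(vb))
  va <- va[seq_len(n)]; vb <- vb[seq_len(n)]
  if (n / a@rate < 2 * maxLag)
    stop("overlap must be at least twice the maximum lag")
  if (!is.null(band)) {
    va <- .zeroPhaseButter(va, a@rate, band, "pass")
    vb <- .zeroPhaseButter(vb, a@rate, band, "pass")
  }
  L <- round(maxLag * a@rate)
  new("Correlogram", lags = (-L:L) / a@rate,
      values = .pearsonXcorr(va, vb, L), counts = numeric(),
      kind = "amplitude",
      band = if (is.null(band)) numeric() else as.numeric(band))
}

#' Spike-train cross-correlogram
#'
#' Histogram of all pairwise spike-time differences t_b - t_a within
#' +/- maxLag, in bins centered on integer multiples of \code{binWidth}.
#' Raw pair counts are kept in \code{counts}; \code{values} holds counts
#' normalized by n_a * n_b * binWidth / duration (the expectation for
#' independent trains), so 1 means chance coincidence.
#'
#' @param a,b \linkS4class{SpikeSet}s (nonempty)
#' @param maxLag largest lag in seconds
#' @param binWidth bin width in seconds; default 5 ms for traces sampled
#'   at >= 200 Hz, else 2 sample periods
#' @return a \linkS4class{Correlogram} of kind "spike"
#' @export
spikeXcorr <- function(a, b, maxLag, binWidth = NULL) {
  stopifnot(is(a, "SpikeSet"), is(b, "SpikeSet"))
  if (nEvents(a) == 0 || nEvents(b) == 0)
    stop("spike cross-correlation needs nonempty spike sets")
  if (is.null(binWidth))
    binWidth <- if (a@rate >= 200) 0.005 else 2 / a@rate
  if (binWidth <= 0) stop("binWidth must be > 0")
  M <- round(maxLag / binWidth)
  centers <- (-M:M) * binWidth
  d <- as.vector(outer(b@peakTimes, a@peakTimes, "-"))
  d <- d[abs(d) <= maxLag]
  bins <- pmin(pmax(round(d / binWidth), -M), M)
  counts <- as.numeric(table(factor(bins, levels = -M:M)))
  dur <- max(a@duration, b@duration)
  expect <- nEvents(a) * nEvents(b) * binWidth / dur
  new("Correlogram", lags = centers, values = counts / expect,
      counts = counts, kind = "spike", band = numeric())
}

#' Instantaneous-amplitude (Hilbert envelope) cross-correlation
#'
#' Both traces are band-passed, their analytic-signal magnitudes
#' (Hilbert envelopes, the "instantaneous amplitude") computed, filter
#' and envelope edge transients trimmed (1 / low-edge seconds at each
#' end), and the envelopes cross-correlated per lag as in
#' \code{\link{amplitudeXcorr}}. Useful for comparing slow activity
#' envelopes of fast carriers, e.g. in compound or LFP-like signals.
#'
#' @param a,b traces of equal rate
#' @param maxLag largest lag in seconds
#' @param band c(low, high) band-pass edges in Hz (required)
#' @return a \linkS4class{Correlogram} of kind "instantaneous"
#' @export
instantaneousXcorr <- function(a, b, maxLag, band) {
  stopifnot(is(a, "VoltTrace"), is(b, "VoltTrace"))
  if (abs(a@rate - b@rate) > 1e-9)
    stop("rates differ; resample one trace first")
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2])
    stop("band must be c(low, high) with 0 < low < high")
  rate <- a@rate
  n <- min(length(a@values), length(b@values))
  trim <- ceiling(rate / band[1])
  L <- round(maxLag * rate)
  if (n - 2 * trim < max(2 * L + 3, 8))
    stop("trace too short for this band: edge transients leave too few samples")
  env <- function(v) {
    bp <- .zeroPhaseButter(v[seq_len(n)], rate, band, "pass")
    e <- Mod(.analyticSignal(bp))
    e[(trim + 1):(n - trim)]
  }
  ea <- env(a@values); eb <- env(b@values)
  ## an envelope whose fluctuation is below 1% of its level carries no
  ## amplitude information (constant-amplitude carrier up to filter and
  ## transform ripple)
  if (stats::sd(ea) < 0.01 * mean(abs(ea)) ||
      stats::sd(eb) < 0.01 * mean(abs(eb)))
    stop("zero-variance envelope (constant-amplitude carrier?)")
  new("Correlogram", lags = (-L:L) / rate,
      values = .pearsonXcorr(ea, eb, L), counts = numeric(),
      kind = "instantaneous", band = as.numeric(band))
}

## Analytic signal via the frequency-domain construction: positive
## frequencies doubled, negative zeroed.
.analyticSignal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}
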