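#' @include events.R
NULL

#' One-sided power spectral density
#'
#' The trace is mean-removed, split into Hann-tapered segments (one
#' segment spanning the whole trace for the plain periodogram; segments
#' of \code{segmentLength} seconds with 50\% overlap for the
#' averaged-segment estimator), and the per-segment periodograms are
#' averaged. Density normalization: the integral of power over frequency
#' approximates the variance of the tapered trace, so a white-noise trace
#' of variance 1 integrates to about 1.
#'
#' @param trace any trace with >= 8 samples
#' @param method "averaged_segment" (default) or "periodogram"
#' @param segmentLength segment length in seconds (averaged_segment only)
#' @return a \linkS4class{PowerSpectrum}
#' @export
powerSpectrum <- function(trace, method = c("averaged_segment", "periodogram"),
                          segmentLength = 10) {
  stopifnot(is(trace, "VoltTrace"))
  method <- match.arg(method)
  x <- trace@values - mean(trace@values)
  n <- length(x)
  if (n < 8) stop("power spectrum needs at least 8 samples")
  rate <- trace@rate
  if (method == "periodogram") {
    L <- n
    segLen <- NA_real_
  } else {
    L <- round(segmentLength * rate)
    if (L > n) stop("segment longer than the trace")
    if (L < 8) stop("segment shorter than 8 samples")
    segLen <- segmentLength
  }
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))  # Hann
  step <- max(1L, floor(L / 2))
  starts <- seq(1L, n - L + 1L, by = step)
  nb <- floor(L / 2) + 1L
  acc <- numeric(nb)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    p <- Mod(stats::fft(seg))^2 / (rate * sum(w^2))
    half <- p[seq_len(nb)]
    ## one-sided: double all bins except DC (and Nyquist when L is even)
    dbl <- rep(2, nb); dbl[1] <- 1
    if (L %% 2 == 0) dbl[nb] <- 1
    acc <- acc + half * dbl
  }
  new("PowerSpectrum", freqs = (seq_len(nb) - 1) * rate / L,
      power = acc / length(starts), method = method, segmentLength = segLen)
}

#' Frequency of maximal power
#'
#' @param spectrum a \linkS4class{PowerSpectrum}
#' @param band optional c(low, high) in Hz restricting the search; must
#'   lie within the spectrum span and contain at least one bin
#' @return peak frequency in Hz (lowest frequency on ties)
#' @export
peakFrequency <- function(spectrum, band = NULL) {
  stopifnot(is(spectrum, "PowerSpectrum"))
  f <- spectrum@freqs; p <- spectrum@power
  if (!is.null(band)) {
    if (length(band) != 2 || band[1] > band[2] ||
        band[1] < f[1] - 1e-12 || band[2] > f[length(f)] + 1e-12)
      stop("band must be c(low, high) within the spectrum span")
    keep <- f >= band[1] & f <= band[2]
    if (!any(keep)) stop("band contains no frequency bins")
    f <- f[keep]; p <- p[keep]
  }
  f[which.max(p)]  # which.max returns the first (lowest-frequency) maximum
}
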