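#' @include pipeline.R
NULL

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("FrameStack: %d frames of %d x %d px @ %g Hz (%.3g s)\n",
              d[1], d[2], d[3], object@rate, d[1] / object@rate))
  if (nzchar(object@originPath))
    cat("  origin:", object@originPath, "\n")
})

setMethod("show", "VoltTrace", function(object) {
  cat(sprintf("%s '%s': %d samples @ %g Hz (%.3g s)\n", class(object),
              object@label, length(object@values), object@rate,
              length(object@values) / object@rate))
  if (length(object@steps)) {
    ops <- vapply(object@steps, function(s) s$op, character(1))
    cat("  steps:", paste(ops, collapse = " -> "), "\n")
  }
})

setMethod("show", "Roi", function(object) {
  cat(sprintf("Roi '%s' (%s)\n", object@label, object@kind))
})

setMethod("show", "BaselineModel", function(object) {
  cat(sprintf("BaselineModel (%s), %d fitted samples\n", object@kind,
              length(object@fitted)))
})

setMethod("show", "SpikeSet", function(object) {
  cat(sprintf("SpikeSet: %d spikes over %.3g s", length(object@peakTimes),
              object@duration))
  if (length(object@peakTimes))
    cat(sprintf(", median amplitude %.4g", stats::median(object@amplitudes)))
  cat("\n")
})

setMethod("show", "BurstSet", function(object) {
  cat(sprintf("BurstSet: %d bursts\n", nrow(object@table)))
  if (nrow(object@table)) print(utils::head(object@table, 5))
})

setMethod("show", "DecayFit", function(object) {
  cat(sprintf("DecayFit: a = %.4g, b = %.4g /s, tau = %.4g s (rss %.3g)\n",
              object@a, object@b, object@tau, object@rss))
})

setMethod("show", "EventShape", function(object) {
  cat(sprintf("EventShape: mean of %d events, window -%g..+%g s (%d excluded)\n",
              object@nEvents, object@pre, object@post, object@nExcluded))
})

setMethod("show", "PowerSpectrum", function(object) {
  cat(sprintf("PowerSpectrum (%s): %d bins, 0..%.4g Hz, peak at %.4g Hz\n",
              object@method, length(object@freqs), max(object@freqs),
              object@freqs[which.max(object@power)]))
})

setMethod("show", "Correlogram", function(object) {
  pk <- object@lags[which.max(object@values)]
  cat(sprintf("Correlogram (%s): lags %.4g..%.4g s, peak at %+.4g s\n",
              object@kind, min(object@lags), max(object@lags), pk))
})

setMethod("show", "ShiftSeries", function(object) {
  cat(sprintf("ShiftSeries: %d frames, max |shift| %.3g px\n",
              nrow(object@shifts), max(abs(object@shifts))))
})

setMethod("show", "SynthSpec", function(object) {
  cat(sprintf("SynthSpec: %g s @ %g Hz, %d components, noise SD %g%s\n",
              object@duration, object@rate, length(object@components),
              object@noiseSd, if (object@invert) ", inverted" else ""))
})
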