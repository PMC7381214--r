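#' @include provenance.R
NULL

#' Read a multi-page grayscale TIFF movie
#'
#' Pages become frames in file order (page i is frame i). Integer TIFFs
#' (8/16-bit) are returned with their raw integer pixel values; 32-bit
#' float TIFFs with the stored float values.
#'
#' @param path path to the TIFF file
#' @param rate acquisition rate in Hz (TIFF metadata is not trusted for
#'   timing; the rate must be supplied)
#' @return a \linkS4class{FrameStack}
#' @export
readStack <- function(path, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("rate must be a single positive number (Hz)")
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1))))
    stop("unsupported format: multi-channel (RGB) TIFF pages; expected grayscale")
  fmt <- attr(pages[[1]], "sample.format")
  if (is.null(fmt) || !identical(fmt, "float")) {
    ## integer samples: re-read unscaled to preserve raw pixel values
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  pages <- lapply(pages, function(p) {
    attributes(p)[setdiff(names(attributes(p)), "dim")] <- NULL
    p
  })
  FrameStack(pages, rate = rate, originPath = path)
}

#' Write a FrameStack as a multi-page grayscale TIFF
#'
#' Integer-valued stacks are stored losslessly as 8-bit (range 0..255) or
#' 16-bit (range 0..65535) unsigned integers; other data must lie in
#' [0, 1] and are stored as 32-bit float (read back at single precision).
#'
#' @param stack a \linkS4class{FrameStack}
#' @param path output path
#' @return the path, invisibly
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "FrameStack"))
  d <- stack@data
  frames <- lapply(seq_len(dim(d)[1]), function(i) d[i, , ])
  isInt <- all(d == round(d)) && min(d) >= 0
  if (isInt && max(d) <= 255) {
    frames <- lapply(frames, function(m) m / 255)
    tiff::writeTIFF(frames, path, bits.per.sample = 8L)
  } else if (isInt && max(d) <= 65535) {
    frames <- lapply(frames, function(m) m / 65535)
    tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  } else if (min(d) >= 0 && max(d) <= 1) {
    tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  } else {
    stop(paste("stack is neither integer-valued in [0, 65535] nor float in",
               "[0, 1]; rescale before writing"))
  }
  invisible(path)
}

#' Read an electrode trace from delimited text
#'
#' Accepts one numeric column (membrane potential, mV; \code{rate}
#' required) or two columns (time in seconds, mV; the rate is inferred as
#' 1 / median inter-sample interval and the time steps must be uniform to
#' within 1\%). Comma, tab and whitespace delimiters are detected
#' automatically; a non-numeric first row is treated as a header.
#'
#' @param path path to the text file
#' @param rate sampling rate in Hz; required for one-column files,
#'   optional (checked against the time column) otherwise
#' @return an \linkS4class{ElectrodeTrace} with offset 0
#' @export
readElectrodeTrace <- function(path, rate = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  hasHeader <- {
    fields <- strsplit(trimws(first), if (sep == "") "[[:space:]]+" else sep)[[1]]
    any(is.na(suppressWarnings(as.numeric(fields))))
  }
  df <- utils::read.table(path, sep = sep, header = hasHeader)
  if (ncol(df) > 2L) stop("expected one (mV) or two (s, mV) columns")
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("non-numeric rows in electrode trace file")
  if (nrow(df) < 2L) stop("an electrode trace needs at least 2 samples")
  if (ncol(df) == 2L) {
    dt <- diff(df[[1]])
    if (any(dt <= 0)) stop("time column must be strictly increasing")
    med <- stats::median(dt)
    if (max(abs(dt - med)) > 0.01 * med)
      stop("inconsistent time steps (beyond 1% tolerance); cannot infer rate")
    inferred <- 1 / med
    if (!is.null(rate) && abs(rate - inferred) > 0.01 * inferred)
      stop(sprintf("given rate %g Hz contradicts time column (%g Hz)",
                   rate, inferred))
    rate <- inferred
    values <- df[[2]]
  } else {
    if (is.null(rate)) stop("rate is required for one-column files")
    values <- df[[1]]
  }
  ElectrodeTrace(values, rate = rate, offset = 0)
}

#' Write an electrode trace as two-column CSV (time_s, mv)
#'
#' @param trace an \linkS4class{ElectrodeTrace}
#' @param path output path
#' @export
writeElectrodeTrace <- function(trace, path) {
  stopifnot(is(trace, "ElectrodeTrace"))
  df <- data.frame(time_s = timeAxis(trace), mv = traceValues(trace))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## ---- tabular views ------------------------------------------------------

#' @describeIn asTable raw trace: time_s, intensity
#' @export
setMethod("asTable", "RawTrace", function(x, ...) {
  data.frame(time_s = timeAxis(x), intensity = traceValues(x))
})

#' @describeIn asTable processed trace: time_s, dff_pct (percent dF/F)
#' @export
setMethod("asTable", "ProcessedTrace", function(x, ...) {
  data.frame(time_s = timeAxis(x), dff_pct = 100 * traceValues(x))
})

#' @describeIn asTable electrode trace: time_s (offset applied), mv
#' @export
setMethod("asTable", "ElectrodeTrace", function(x, ...) {
  data.frame(time_s = timeAxis(x) + x@offset, mv = traceValues(x))
})

#' @describeIn asTable spikes: time_s, amplitude, tau_decay_s
#' @export
setMethod("asTable", "SpikeSet", function(x, ...) {
  data.frame(time_s = x@peakTimes, amplitude = x@amplitudes,
             tau_decay_s = x@tauDecay)
})

#' @describeIn asTable bursts: start_s, end_s, duration_s, a_max,
#'   t_peak_s, tau_decay_s
#' @export
setMethod("asTable", "BurstSet", function(x, ...) {
  tb <- x@table
  data.frame(start_s = tb$start, end_s = tb$end, duration_s = tb$duration,
             a_max = tb$aMax, t_peak_s = tb$tPeak, tau_decay_s = tb$tauDecay)
})

#' @describeIn asTable spectrum: freq_hz, power
#' @export
setMethod("asTable", "PowerSpectrum", function(x, ...) {
  data.frame(freq_hz = x@freqs, power = x@power)
})

#' @describeIn asTable correlogram: lag_s, value (plus raw_count for the
#'   spike kind)
#' @export
setMethod("asTable", "Correlogram", function(x, ...) {
  df <- data.frame(lag_s = x@lags, value = x@values)
  if (x@kind == "spike") df$raw_count <- x@counts
  df
})

#' @describeIn asTable event shape: time_s (peak at 0), mean, sd
#' @export
setMethod("asTable", "EventShape", function(x, ...) {
  npre <- round(x@pre * x@rate)
  idx <- seq_along(x@waveform) - 1 - npre
  data.frame(time_s = idx / x@rate, mean = x@waveform, sd = x@sd)
})

#' Export result objects as CSV files
#'
#' Writes one CSV per result (comma separator, '.' decimal, UTF-8, one
#' header row documenting the columns). Values survive a write/read round
#' trip to at least 12 significant digits.
#'
#' @param results a named list of result objects (traces, SpikeSet,
#'   BurstSet, PowerSpectrum, Correlogram, EventShape), or a single such
#'   object
#' @param dir output directory, created if needed
#' @return named character vector: file path per result (the manifest)
#' @export
exportTables <- function(results, dir) {
  if (!is.list(results)) results <- stats::setNames(list(results), "result")
  if (length(results) == 0L) stop("result set is empty")
  if (is.null(names(results)) || any(names(results) == ""))
    stop("every result needs a name")
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory %s", dir))
  manifest <- character()
  for (nm in names(results)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(asTable(results[[nm]]), path, row.names = FALSE)
    manifest[nm] <- path
  }
  manifest
}
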