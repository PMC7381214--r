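#' @include correlate.R
NULL

## ---- component constructors --------------------------------------------

#' Oscillatory component: amp * sin(2 pi freq t)
#' @param freq frequency (Hz)
#' @param amp amplitude in dF/F units
#' @export
oscillation <- function(freq, amp) {
  stopifnot(freq > 0, amp >= 0)
  list(type = "oscillation", freq = freq, amp = amp)
}

#' Spike-train component
#'
#' Two template shapes: \code{"biexp"}, a difference of exponentials
#' exp(-t/tau) - exp(-t/rise) (rise 2 ms by default) whose asymmetry
#' matches how fast GEVIs render action potentials, and
#' \code{"gaussian"}, a symmetric bell of SD \code{width} seconds, the
#' shape spikes take once indicator kinetics and optics have blurred
#' them. Both are normalized so the template peak equals \code{amp}. For
#' the biexp shape \code{times} are onsets; for the gaussian shape they
#' are the peak times.
#'
#' @param times spike times (s), or NULL to draw a Poisson train
#' @param poissonRate mean spike rate (Hz) when \code{times} is NULL
#' @param amp template peak amplitude (dF/F units)
#' @param tau biexp: decay time constant of the falling phase (s)
#' @param rise biexp: rise time constant (s)
#' @param shape "biexp" or "gaussian"
#' @param width gaussian: template SD (s)
#' @export
spikeComponent <- function(times = NULL, poissonRate = NULL, amp = 0.05,
                           tau = 0.02, rise = 0.002,
                           shape = c("biexp", "gaussian"), width = 0.01) {
  shape <- match.arg(shape)
  stopifnot(amp > 0, tau > rise, rise > 0, width > 0)
  if (is.null(times) && is.null(poissonRate))
    stop("give spike times or a Poisson rate")
  list(type = "spikes", times = times, poissonRate = poissonRate, amp = amp,
       tau = tau, rise = rise, shape = shape, width = width)
}

#' Burst component
#'
#' Each burst occupies [start, start + width): a half-cosine rise from 0
#' to \code{aMax} over \code{tPeak} seconds, then exponential decay
#' aMax * exp(-b (t - tPeak)).
#'
#' @param starts burst start times (s)
#' @param width burst envelope width (s)
#' @param aMax peak amplitude (dF/F units)
#' @param tPeak time from burst start to peak (s)
#' @param b decay rate (1/s); the ground-truth tau is 1/b
#' @export
burstComponent <- function(starts, width, aMax = 0.1, tPeak = 0.2, b = 2) {
  stopifnot(all(starts >= 0), width > tPeak, aMax > 0, tPeak > 0, b > 0)
  list(type = "bursts", starts = starts, width = width, aMax = aMax,
       tPeak = tPeak, b = b)
}

#' Construct a SynthSpec
#'
#' @param duration recording length (s)
#' @param rate sampling rate (Hz)
#' @param components list of components from \code{\link{oscillation}},
#'   \code{\link{spikeComponent}}, \code{\link{burstComponent}}
#' @param bleach c(a, b) of the photobleaching baseline a * exp(-b * t)
#'   (a.u.; a is the resting fluorescence level)
#' @param noiseSd additive Gaussian noise SD (a.u., on the fluorescence
#'   scale)
#' @param invert emulate an indicator that dims on depolarization
#' @param seed RNG seed
#' @export
SynthSpec <- function(duration = 10, rate = 100, components = list(),
                      bleach = c(a = 100, b = 0.02), noiseSd = 0,
                      invert = FALSE, seed = 1L) {
  new("SynthSpec", duration = duration, rate = rate, components = components,
      bleach = stats::setNames(as.numeric(bleach), c("a", "b")),
      noiseSd = noiseSd, invert = invert, seed = as.integer(seed))
}

## ---- trace synthesis ----------------------------------------------------

## Clean dF/F signal plus ground-truth tables for one spec. RNG is only
## used for Poisson spike times, from the spec seed.
.synthSignal <- function(spec) {
  n <- round(spec@duration * spec@rate)
  t <- (seq_len(n) - 1) / spec@rate
  sig <- numeric(n)
  spikes <- list(); bursts <- list()
  for (comp in spec@components) {
    if (comp$type == "oscillation") {
      sig <- sig + comp$amp * sin(2 * pi * comp$freq * t)
    } else if (comp$type == "spikes") {
      times <- comp$times
      if (is.null(times)) {
        nSp <- stats::rpois(1, comp$poissonRate * spec@duration)
        times <- sort(stats::runif(nSp, 0, spec@duration))
      }
      shape <- comp$shape %||% "biexp"
      peakT <- numeric(length(times))
      for (k in seq_along(times)) {
        rel <- t - times[k]
        if (shape == "gaussian") {
          idx <- which(abs(rel) <= 5 * comp$width)
          tmpl <- comp$amp * exp(-rel[idx]^2 / (2 * comp$width^2))
        } else {
          tf <- comp$tau; tr <- comp$rise
          tp <- log(tf / tr) * tr * tf / (tf - tr)  # template peak time
          norm <- exp(-tp / tf) - exp(-tp / tr)
          idx <- which(rel >= 0)
          tmpl <- comp$amp / norm *
            (exp(-rel[idx] / tf) - exp(-rel[idx] / tr))
        }
        sig[idx] <- sig[idx] + tmpl
        ## ground truth uses the sampled template peak, the best any
        ## detector can do on the discrete grid
        peakT[k] <- t[idx[which.max(tmpl)]]
      }
      if (length(times))
        spikes[[length(spikes) + 1L]] <- data.frame(
          time_s = peakT, amplitude = comp$amp)
    } else if (comp$type == "bursts") {
      for (on in comp$starts) {
        rel <- t - on
        riseIdx <- rel >= 0 & rel < comp$tPeak
        fallIdx <- rel >= comp$tPeak & rel < comp$width
        sig[riseIdx] <- sig[riseIdx] +
          comp$aMax * 0.5 * (1 - cos(pi * rel[riseIdx] / comp$tPeak))
        sig[fallIdx] <- sig[fallIdx] +
          comp$aMax * exp(-comp$b * (rel[fallIdx] - comp$tPeak))
      }
      bursts[[length(bursts) + 1L]] <- data.frame(
        start_s = comp$starts, end_s = comp$starts + comp$width,
        a_max = comp$aMax, t_peak_s = comp$tPeak, tau_decay_s = 1 / comp$b)
    }
  }
  list(t = t, signal = sig,
       spikes = if (length(spikes)) do.call(rbind, spikes) else
         data.frame(time_s = numeric(), amplitude = numeric()),
       bursts = if (length(bursts)) do.call(rbind, bursts) else
         data.frame(start_s = numeric(), end_s = numeric(), a_max = numeric(),
                    t_peak_s = numeric(), tau_decay_s = numeric()))
}

#' Synthesize a raw fluorescence trace with ground truth
#'
#' The fluorescence model is F(t) = bleach(t) * (1 + s * signal(t)) +
#' noise, with bleach(t) = a * exp(-b t), s = -1 for inverting indicators
#' and +1 otherwise, and signal(t) the sum of the requested components in
#' dF/F units. Ground truth uses the same schemas as the analysis
#' outputs, so recovery tests are column-wise comparisons.
#'
#' @param spec a \linkS4class{SynthSpec}
#' @return list: \code{trace} (a \linkS4class{RawTrace}), \code{truth}
#'   (list with \code{signal} — the clean dF/F vector —, \code{bleach},
#'   \code{spikes} and \code{bursts} tables)
#' @export
synthTrace <- function(spec) {
  stopifnot(is(spec, "SynthSpec"))
  validObject(spec)
  set.seed(spec@seed)
  parts <- .synthSignal(spec)
  s <- if (spec@invert) -1 else 1
  bleach <- spec@bleach[["a"]] * exp(-spec@bleach[["b"]] * parts$t)
  F <- bleach * (1 + s * parts$signal)
  if (spec@noiseSd > 0)
    F <- F + stats::rnorm(length(F), 0, spec@noiseSd)
  list(trace = RawTrace(F, rate = spec@rate, label = "synth"),
       truth = list(signal = parts$signal, bleach = bleach,
                    spikes = parts$spikes, bursts = parts$bursts))
}

## ---- movie synthesis ----------------------------------------------------

#' Describe one cell of a synthetic movie
#'
#' @param center c(row, col) of the soma, 1-based pixel coordinates
#' @param sigma Gaussian kernel SD in pixels
#' @param spec the cell's \linkS4class{SynthSpec}
#' @export
synthCell <- function(center, sigma, spec) {
  stopifnot(length(center) == 2, sigma > 0, is(spec, "SynthSpec"))
  list(center = as.numeric(center), sigma = sigma, spec = spec)
}

#' Synthesize a movie with known ground truth
#'
#' Every cell is a Gaussian spatial kernel (peak 1 at its center)
#' modulated by its fluorescence trace. Scattered-light
#' cross-contamination is emulated by the mixing matrix \code{scatter}:
#' the trace displayed under cell i's kernel is
#' sum_j scatter[i, j] * trace_j (identity = no contamination). Rigid
#' movement is emulated by rolling each frame by its (row, col) shift —
#' integer shifts roll exactly, fractional shifts use bilinear
#' interpolation. Pixel noise is added last; with \code{quantize = TRUE}
#' (default) intensities are rounded to integer counts so the movie
#' survives a TIFF round trip bit-exactly.
#'
#' @param cells list of \code{\link{synthCell}} entries; all specs must
#'   share duration and rate
#' @param shape frame shape c(rows, cols)
#' @param movement optional nFrames x 2 matrix of per-frame (row, col)
#'   shifts
#' @param scatter optional mixing matrix (nCells x nCells, coefficients
#'   >= 0)
#' @param offset background intensity level (a.u.)
#' @param noiseSd per-pixel Gaussian noise SD
#' @param seed RNG seed (movie-level noise; cell traces use their own
#'   spec seeds)
#' @param quantize round intensities to integer counts
#' @return list: \code{stack} (a \linkS4class{FrameStack}), \code{truth}
#'   (cell traces clean and mixed, kernels, shifts, masks)
#' @export
synthMovie <- function(cells, shape, movement = NULL, scatter = NULL,
                       offset = 20, noiseSd = 0, seed = 1L, quantize = TRUE) {
  stopifnot(length(cells) >= 1, length(shape) == 2)
  nc <- length(cells)
  dur <- unique(vapply(cells, function(c) c$spec@duration, numeric(1)))
  rate <- unique(vapply(cells, function(c) c$spec@rate, numeric(1)))
  if (length(dur) != 1 || length(rate) != 1)
    stop("all cells must share duration and rate")
  nf <- round(dur * rate)
  rows <- shape[1]; cols <- shape[2]
  for (cl in cells) {
    if (cl$center[1] < 1 || cl$center[1] > rows ||
        cl$center[2] < 1 || cl$center[2] > cols)
      stop("cell kernel center outside the frame")
  }
  if (is.null(scatter)) scatter <- diag(nc)
  scatter <- as.matrix(scatter)
  if (any(dim(scatter) != c(nc, nc)) || any(scatter < 0))
    stop("scatter must be an nCells x nCells matrix with coefficients >= 0")
  if (!is.null(movement)) {
    movement <- as.matrix(movement)
    if (any(dim(movement) != c(nf, 2)))
      stop("movement must be an nFrames x 2 matrix")
  }

  traces <- vapply(cells, function(cl) synthTrace(cl$spec)$truth$signal,
                   numeric(nf))
  traces <- matrix(traces, nrow = nf)
  ## fluorescence per cell: bleach * (1 + s * signal), no pixel noise here
  fluo <- vapply(seq_len(nc), function(i) {
    sp <- cells[[i]]$spec
    s <- if (sp@invert) -1 else 1
    t <- (seq_len(nf) - 1) / rate
    sp@bleach[["a"]] * exp(-sp@bleach[["b"]] * t) * (1 + s * traces[, i])
  }, numeric(nf))
  fluo <- matrix(fluo, nrow = nf)
  mixed <- fluo %*% t(scatter)

  kernels <- lapply(cells, function(cl) {
    rr <- matrix(seq_len(rows), rows, cols)
    cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    exp(-((rr - cl$center[1])^2 + (cc - cl$center[2])^2) / (2 * cl$sigma^2))
  })

  set.seed(as.integer(seed))
  data <- array(0, c(nf, rows, cols))
  base <- matrix(offset, rows, cols)
  for (f in seq_len(nf)) {
    frame <- base
    for (i in seq_len(nc)) frame <- frame + kernels[[i]] * mixed[f, i]
    if (!is.null(movement)) {
      d <- movement[f, ]
      frame <- if (all(d == round(d))) .rollFrame(frame, d[1], d[2])
               else .translateFrame(frame, d[1], d[2])
    }
    if (noiseSd > 0)
      frame <- frame + matrix(stats::rnorm(rows * cols, 0, noiseSd), rows, cols)
    if (quantize) frame <- pmax(round(frame), 0)
    data[f, , ] <- frame
  }
  list(stack = FrameStack(data, rate = rate),
       truth = list(signal = traces, fluo = fluo, mixed = mixed,
                    kernels = kernels,
                    shifts = if (is.null(movement)) matrix(0, nf, 2)
                             else movement))
}

## circular roll (content moves by +dr rows, +dc cols)
.rollFrame <- function(frame, dr, dc) {
  nr <- nrow(frame); nc <- ncol(frame)
  ri <- ((seq_len(nr) - 1 - dr) %% nr) + 1
  ci <- ((seq_len(nc) - 1 - dc) %% nc) + 1
  frame[ri, ci]
}
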