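---
title: "Methods: from fluorescence movies to spikes, bursts and correlograms"
author: "optovolt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from fluorescence movies to spikes, bursts and correlograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optovolt)
```

## The analysis problem

Genetically encoded voltage indicators (GEVIs) turn membrane potential
into fluorescence, so a camera pointed at a labelled circuit records the
electrical activity of every visible cell at once. The raw material is a
single-channel movie: `F` frames of `H x W` intensities at a known frame
rate. Between that movie and any physiological statement stand several
confounds — photobleaching, scattered light from neighboring cells,
brain movement, shot noise — and several derived quantities:
normalized dF/F traces, detected spikes and bursts with their kinetics,
power spectra, and the temporal relations between cells. optovolt
implements this chain headlessly, with every stage testable against
synthetic ground truth.

## Processing model and its fixed order

A trace passes through stages in one fixed order:

crop -> background subtraction -> baseline / dF/F -> filtering ->
resampling.

The order is not cosmetic. Background subtraction must see raw
intensities (it operates on additive scattered light); the baseline
must be fitted before normalization (it *is* the normalizer); filtering
a trace and then cropping it would let edge transients move into the
analysis window; resampling last keeps every earlier stage at the native
rate. Each trace carries a provenance list of the applied steps, and the
package refuses out-of-order applications rather than silently
reordering. One configuration applied to many ROIs yields provenance
lists identical up to the ROI label, which is what makes multicellular
comparisons legitimate.

### ROIs and background

ROIs are rectangles, ellipses or polygons in pixel coordinates
(1-based, pixel center at integer coordinates). Membership of curved
shapes uses the pixel-center rule — a pixel belongs iff its center lies
inside or on the boundary — because it is deterministic and can be
checked against a brute-force point-in-polygon oracle; there is no
antialiased partial weighting. The perisomatic background of a cell is
its ROI mask dilated by a configurable width (Chebyshev metric, i.e. a
square structuring element; the metric is a package choice, any small
neighborhood works) minus the ROI and minus any excluded neighbor
masks. Background subtraction removes
`scale * (background - mean(background))`: centering the background
first means the subtraction removes fluctuations, not the level, so the
baseline fit that follows is unaffected. The scale is a fraction in
[0, 1]; 1 assumes the annulus carries the contaminant at the same
strength as the ROI.

### Baseline and dF/F

Baseline families: polynomials of chosen degree, a mono-exponential
`a*exp(-b*t) + c` (the photobleaching model; the decay rate is
constrained nonnegative), a bi-exponential for recordings with two
bleaching pools, and a marker-guided monotone cubic spline for traces
whose drift defies a global parametric form. The spline anchors at the
5-sample local median of the trace around each user-set marker —
markers are meant to be placed *between* events, and the local median
makes the anchor robust to a stray event sample; beyond the outermost
markers the baseline continues at the anchor value. All least-squares
families are checked to fit at least as well as a constant mean.

dF/F is `(F - F0)/F0` with `F0` the fitted baseline value per sample —
the standard normalization, consistent with reporting percent changes.
Many GEVIs (ArcLight-like) dim on depolarization, so an inversion flag
multiplies the result by -1; applying it twice restores the original.

### Filtering

Band filters are Butterworth of order 3 applied forward-backward
(`filtfilt`), so they are zero-phase: an in-band sinusoid keeps its
peak positions exactly, which matters because event *times* are the
scientific output. Savitzky-Golay smoothing (odd window, polynomial
order below the window) preserves polynomial trends and, importantly,
peak amplitudes better than a plain moving average; the moving average
is available with a flat or Hann taper and renormalizes its truncated
window at the edges so constants pass through unchanged. Corner
frequencies at the Nyquist limit are nudged just below it for a stable
design.

### Resampling and modality alignment

Resampling evaluates the trace at `k/newRate` within the original span
(linear or cubic spline interpolation). Two workflow rules suggest the
minimum sensible target rate: resolving event *intervals* needs twice
the signal frequency (Nyquist), resolving event *shape* needs at least
10 samples per shortest event; the combined suggestion takes the larger
of the two — the only combination that violates neither rule.
Electrode recordings (e.g. simultaneous patch clamp) are aligned to the
optical clock by a signed offset; joint analyses interpolate the
electrode trace onto the optical grid over the overlap window only.

## Movement correction

Rigid translation only: for each frame the integer displacement in
`[-maxShift, maxShift]^2` maximizing the Pearson correlation with the
reference image (first frame, mean image, or a chosen frame) over the
overlap region, refined to subpixel precision by a 1-D quadratic fit
through the correlation peak and its axis neighbors. The refinement is
skipped when the integer peak is already a perfect correlation —
a parabola through a perfect peak would only be biased by its larger
neighbor. Correction translates each frame by the negated displacement
with bilinear interpolation, filling uncovered pixels with the frame
median. Exhaustive search is exact by construction (the oracle tests
compare it against an independent implementation), affordable because
movie frames here are small, and free of the wrap-around artifacts of
FFT correlation. Non-rigid deformation is out of scope; the corrected
stack is a first-class object writable back to TIFF.

## Event detection

**Thresholds.** Static: a constant level. Dynamic: a centered moving
average over a window `w` (default 1 s) plus `k` (default 3) times the
noise SD. The noise SD is estimated as `sd(diff(x))/sqrt(2)` — the
first difference cancels slow structure (oscillations, residual drift)
and for white noise has variance twice the noise variance. This
estimator *assumes the noise is white*: on a smoothed trace it
underestimates. The recommended workflow is therefore to compute the
threshold on the unsmoothed trace and detect on a smoothed copy; the
spike-fidelity tests exercise exactly that combination.

**Spikes.** Each maximal run of samples strictly above the threshold
yields exactly one spike at its maximum (earliest index on ties); peaks
closer than the refractory period keep the larger amplitude. A spike's
amplitude is its peak value minus the threshold at the peak sample, so
slow baseline undulation does not inflate amplitudes. Hyperpolarization
events are detected by running the same machinery on the sign-flipped
trace (`polarity = "negative"`).

**Bursts.** A burst opens at an upward threshold crossing and closes
when the trace falls below
`threshold + endFraction * (A_max - threshold)` and stays below for at
least 3 samples (hysteresis against noise re-crossings); bursts shorter
than `minDuration` are dropped. Small `endFraction` keeps the decay
tail inside the burst (use ~0.1 when the decay constant is the target),
large values end bursts near the peak. Per burst the package reports
duration, the maximum amplitude `A_max`, the time from burst start to
peak `t_peak`, and the decay constant `tau_decay`. Note `t_peak` is
measured from the threshold crossing, which trails the biophysical
event onset by the time the rise needs to reach threshold.

**Decay kinetics.** `tau_decay` comes from a nonlinear least-squares
fit of `a*exp(-b*x)` to the samples from the peak to the burst end
(Levenberg-Marquardt, initialized at `a0` = first sample,
`b0` = 1/segment duration, parameter tolerance 1e-8, at most 200
iterations), with `tau = 1/b` — an identity that holds bit-exactly in
every fit object. Fits with nonpositive `a` or `b` are rejected; burst
tables carry `NA` where the fit failed (e.g. a flat-topped pulse with
no decay).

**Event shapes.** Windows `[-pre, +post]` around each peak, aligned on
the peak sample, averaged pointwise with a per-sample SD; events whose
window would leave the trace are excluded and counted. Averaging n
events suppresses independent noise by `1/sqrt(n)`, which the tests
verify across n = 4, 16, 64.

## Spectra

Power spectra are one-sided densities from mean-removed, Hann-tapered
segments; the plain periodogram uses one whole-trace segment, the
default averaged-segment estimator uses 10 s segments with 50% overlap
(shorter segments trade frequency resolution for variance). The
normalization makes the integral of power over frequency approximate
the trace variance, so a unit-variance white-noise trace integrates to
about 1 (checked to 10%). Peak frequency is the argmax bin, optionally
within a band, ties resolved toward the lower frequency.

## Cross-correlation

Three modes, one sign convention: a positive lag means the second
argument follows the first.

* **Amplitude**: Pearson correlation of `a(t)` with `b(t + lag)` over
  the overlapping samples, per lag. The per-lag normalization keeps
  every value in [-1, 1] (unlike FFT-based covariance estimates) at
  O(lags x samples) cost, which is negligible at recording scale. An
  optional band-pass restricts the comparison to a frequency band.
* **Spike**: the histogram of all pairwise spike-time differences
  within the lag range, bins centered on multiples of the bin width
  (default 5 ms at rates of at least 200 Hz, else two sample periods).
  Raw counts are kept alongside counts normalized by
  `n_a * n_b * binWidth / duration`, the chance-coincidence rate.
* **Instantaneous amplitude**: both traces are band-passed, their
  Hilbert envelopes (analytic-signal magnitudes) taken, edge transients
  of `1/f_low` seconds trimmed at each end, and the envelopes
  correlated as above. This compares slow activity envelopes of fast
  carriers, as in compound or LFP-like signals. An envelope whose
  fluctuation is below 1% of its level is rejected as carrying no
  amplitude information (a constant-amplitude carrier produces only
  filter ripple).

## The synthetic-data generator

`synthTrace` builds `F(t) = bleach(t) * (1 + s * signal(t)) + noise`:
an exponential photobleaching baseline multiplied by one plus the
summed dF/F signal (`s = -1` for inverting indicators) plus white
Gaussian noise. Components: sinusoidal oscillations; spike trains with
either a difference-of-exponentials template (fast rise, slower fall —
the asymmetry of fast GEVIs) or a Gaussian template (the shape spikes
take after indicator kinetics and optics have blurred them); bursts
with a half-cosine rise to `A_max` over `t_peak` and an exponential
decay of rate `b`. Ground-truth tables use the same column schemas as
the analysis outputs, so recovery tests are column-wise comparisons;
spike ground truth records the *sampled* template peak, the best any
detector can do on the discrete grid. All randomness flows from the
spec's single seed; equal specs are bit-identical.

`synthMovie` renders cells as Gaussian kernels (peak 1) modulated by
their fluorescence traces, cross-mixed by a scatter matrix (entry
`[i, j]` is the fraction of cell j's trace appearing under cell i's
kernel), over a constant offset, rolled per frame by a movement series
(integer shifts roll exactly; fractional shifts interpolate
bilinearly), plus per-pixel noise, quantized to integer counts by
default so movies survive a TIFF round trip bit-exactly.

What the generator deliberately does **not** emulate: photon (Poisson)
noise statistics, indicator nonlinearity and state-dependent kinetics,
non-rigid tissue deformation, focus drift, and spatially structured
backgrounds. Passing tests therefore demonstrate the correctness of
the algorithms under their stated models, not robustness to every
artifact of real recordings.

## Numerical choices and degenerate inputs

* Time: sample 1 sits at t = 0; crops are half-open `[start, end)`.
* TIFF: integer-valued stacks are written losslessly as 8/16-bit;
  float stacks must lie in [0, 1] (stored at single precision). Pixel
  values are read back unscaled.
* CSV export writes full double precision (round trips to better than
  1e-9); dF/F is exported as percent.
* Baseline fits that cannot beat a constant mean raise an error rather
  than returning a misleading curve.
* Zero-variance frames, empty masks, fully occluded annuli, reversed
  crop bounds, out-of-range offsets and empty overlap windows all raise
  immediate errors with the offending condition named.
* The pipeline runner validates its config before touching data and
  names the offending key; identical configs yield byte-identical
  outputs (the run manifest contains versions and a config hash, no
  timestamps).

## Problem sizes in the test-suite and acceptance runs

The suite validates on desk-scale problems chosen to finish in seconds
while leaving no statistical ambiguity: traces of 2 000–10 000 samples
at 25–1000 Hz, movies up to 100 frames of 40 x 40 pixels, 100-replicate
recovery studies, and 100-instance oracle-equivalence sweeps. The
spike-fidelity study uses 20 Gaussian spikes (SD 9 ms) of amplitude 5
noise-SD at 250 Hz over 20 s, a dynamic threshold (1 s window, k = 3)
computed on the raw trace, and detection on the SG(9, 2)-smoothed
trace; this configuration detects all spikes within one sample with no
false positives for the large majority of noise realizations, which is
the property the fixed-seed tests pin down.

## Known limitations

Registration is translation-only and assumes the cell layout is rigid;
the dynamic threshold's noise estimator assumes white noise; decay fits
assume a single exponential after the peak (two-component decays bias
`tau`); the spike correlogram's normalization assumes stationary
trains; and ROI geometry is limited to the three parametric shapes —
hand-drawn and automatically detected ROIs are out of scope.
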