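# optovolt

Headless analysis of voltage-imaging recordings made with genetically
encoded voltage indicators (GEVIs). Starting from a multi-page TIFF
movie (or an imported electrode trace), optovolt extracts per-cell
fluorescence traces, removes the standard confounds of the method —
photobleaching, scattered light from neighbors, rigid brain movement —
and turns the cleaned traces into the quantities optical
electrophysiologists report: dF/F time courses, detected spikes and
bursts with their kinetics, event-triggered average waveforms, power
spectra, and cross-correlograms relating the cells of a circuit in
time. It is aimed at labs doing widefield GEVI imaging (flies, fish,
mice) who want a scriptable, testable pipeline rather than a GUI.

## The model in brief

* **Normalization.** dF/F = (F − F0)/F0 with F0 a fitted baseline:
  polynomial, mono-exponential a·e^(−b·t) + c (photobleaching),
  bi-exponential, or a marker-guided monotone spline. Indicators that
  dim on depolarization are handled by sign inversion.
* **Event kinetics.** Bursts are characterized by duration, maximum
  amplitude A_max, time to peak t_peak, and the decay constant
  τ_decay, obtained by nonlinear least squares of f(x) = a·e^(−b·x)
  on the samples after A_max with τ_decay = 1/b (an identity that
  holds bit-exactly in every fit object).
* **Detection.** Spikes are maxima of runs above a static level or a
  dynamic threshold (moving average over a window w plus k times the
  noise SD, the latter estimated as sd(diff(x))/√2).
* **Temporal relations.** Per-lag Pearson cross-correlation of dF/F
  traces, pairwise-lag histograms of spike trains, and correlation of
  Hilbert envelopes ("instantaneous amplitudes") of band-passed
  traces. Positive lag always means the second signal follows the
  first.
* **Preprocessing order** is fixed and enforced:
  crop → background → baseline/dF/F → filter → resample, and each
  trace carries its provenance.

A full account of the algorithms, parameters and design decisions is in
`vignettes/voltage-imaging-methods.Rmd`.

## Worked example

Synthesize a bursting cell with photobleaching and noise (ground truth
known: bursts start at 3, 8, 13 s with A_max = 0.2 and τ_decay
= 0.5 s), then recover those numbers:

```r
library(optovolt)

spec <- SynthSpec(duration = 20, rate = 100,
                  components = list(burstComponent(starts = c(3, 8, 13),
                                                   width = 2.5, aMax = 0.2,
                                                   tPeak = 0.2, b = 2)),
                  bleach = c(a = 300, b = 0.05), noiseSd = 0.6, seed = 5)
raw <- synthTrace(spec)$trace

## markers between the bursts guide the baseline through event-free data
baseline <- fitBaseline(raw, "marker_spline",
                        markers = round(c(0.5, 6.8, 11.8, 16.8, 19.5) * 100))
dff <- computeDFF(raw, baseline)
dff
#> ProcessedTrace 'synth': 2000 samples @ 100 Hz (20 s)
#>   steps: baseline -> dff

threshold <- makeThreshold(dff, "static", level = 0.02)
bursts <- detectBursts(dff, threshold, minDuration = 0.5, endFraction = 0.1)
bursts
#> BurstSet: 3 bursts
#>   start   end duration      aMax tPeak  tauDecay peakIndex
#> 1  3.06  3.98     0.92 0.1905040  0.13 0.4725967       320
#> 2  8.05  9.03     0.98 0.2047307  0.15 0.4949747       821
#> 3 13.05 14.04     0.99 0.1970280  0.14 0.4992515      1320

powerSpectrum(dff, "averaged_segment", segmentLength = 10)
#> PowerSpectrum (averaged_segment): 501 bins, 0..50 Hz, peak at 0.2 Hz
```

The three bursts are found where they were planted; A_max comes back
within a few percent of 0.2 and τ_decay within a few percent of
0.5 s. (t_peak is measured from the threshold crossing, which trails
the burst onset slightly — hence 0.13–0.15 s against a 0.2 s
onset-to-peak time.) The spectrum peaks at 0.2 Hz, the burst
repetition rate. `exportTables(list(bursts = bursts), "out")` writes
the table as CSV.

Movies work the same way: `readStack` (or `synthMovie`) gives a
`FrameStack`; `estimateShifts`/`applyShifts` correct rigid movement;
`extractTrace` with an ROI and `perisomaticAnnulus` +
`subtractBackground` handle scattered light; `runPipeline` drives the
whole chain from a YAML/JSON config (see
`inst/extdata/example-config.yaml`), and `exec/optovolt` wraps it for
the shell.

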