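# Example optovolt pipeline configuration.
# Stages run in the fixed order: import -> movement correction -> ROI
# extraction -> background -> preprocessing steps -> detection -> analyses.
seed: 1
input:
  tiff: movie.tif       # multi-page grayscale TIFF
  rate: 100             # frames per second
rois:
  - {label: cell1, kind: ellipse, center: [20, 20], semiAxes: [4, 4]}
  - {label: cell2, kind: ellipse, center: [20, 44], semiAxes: [4, 4]}
movement: {reference: first, maxShift: 5}      # optional
background: {width: 2, scale: 1.0}             # optional perisomatic
steps:                                          # ordered; order is enforced
  - {op: crop, start: 0, end: 30}
  - {op: baseline, kind: mono_exponential}
  - {op: dff, invert: true}                     # invert for ArcLight-like GEVIs
  - {op: filter, type: savitzky_golay, window: 9, polyorder: 2}
detection:
  mode: spikes
  threshold: {mode: dynamic, window: 1, k: 3}
  refractory: 0.01
analyses:
  spectrum: {method: averaged_segment, segmentLength: 10}
  xcorr: {kind: amplitude, maxLag: 1}
output: results
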