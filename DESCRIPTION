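Package: optovolt
Title: Analysis of Optical Voltage-Imaging Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Headless analysis of voltage-imaging movies recorded with
    genetically encoded voltage indicators (GEVIs), from multi-page TIFF
    stacks to publishable event tables. Provides region-of-interest trace
    extraction with perisomatic background correction, rigid movement
    correction, photobleaching baseline fitting and dF/F computation,
    zero-phase filtering and resampling, dynamic-threshold spike and burst
    detection with exponential decay kinetics, event-triggered waveform
    averaging, Welch-style power spectra, and amplitude, spike-train and
    Hilbert-envelope cross-correlograms for multicellular temporal-relation
    analysis. Includes a synthetic-data generator with full ground truth and
    a config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    signal,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'provenance.R'
    'io_stack.R'
    'roi.R'
    'preprocess.R'
    'register.R'
    'events.R'
    'spectral.R'
    'correlate.R'
    'optovolt-package.R'
    'synth.R'
    'pipeline.R'
    'show-methods.R'
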