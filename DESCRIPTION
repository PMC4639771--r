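Package: zcia
Title: Zero-Crossing Interval Analysis of Scalp EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for zero-crossing interval analysis of multichannel scalp
    EEG. Band-passes recordings with zero-phase FIR filter banks, detects
    isoelectric-line crossings by linear interpolation, accumulates pooled
    normalized interval histograms (interval spectra), and derives diagnostic
    markers from them: fixed-length interval counts, descriptive statistics,
    and Shannon/min-entropy of the spectrum. Provides nonparametric screening
    of candidate markers (Kruskal-Wallis with Bonferroni correction and
    rank-based Tukey-Kramer post-hoc tests), ROC/AUC machinery with
    leave-pair-out cross-validation and one- or two-step parameter fitting,
    channel-by-segment AUC-ratio maps, segment-length subsampling experiments,
    and vertically averaged ROC curves. Includes a minimal European Data
    Format (EDF) reader/writer and a synthetic interictal EEG cohort
    generator for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
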