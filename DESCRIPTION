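Package: dscnet
Title: Multi-Angle Convolutional Networks for EEG Addiction Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating DSCnet, a compact
    convolutional architecture for two-class EEG decoding built from a
    hybrid-representation embedding, depthwise-separable temporal
    convolutions, a directional adaptive feature modulation (DAFM)
    operator and a contextual-transformer (CoT) attention block.  The
    package covers the full experimental chain: a synthetic multichannel
    EEG generator with a controllable band-power contrast between
    classes, the signal-conditioning pipeline (notch, band-pass,
    resampling, re-referencing, segmentation, per-time-point
    standardization), the network itself with analytic gradients and an
    Adam trainer, subject-aware train/test splitting, confusion-matrix
    metrics, and an ablation runner over the architecture variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    methods,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
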