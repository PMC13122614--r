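Package: wingbeatRadar
Title: Micro-Doppler Radar Classification of Flying Insects
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for taxonomic classification of flying insects from
    continuous-wave millimetre-wave radar reflections. Provides a synthetic
    generator of complex baseband micro-Doppler recordings (harmonic wingbeat
    component, slow body-motion Doppler and noise), signal preprocessing
    (normalisation, Chebyshev high-pass filtering, Hann framing), detection of
    wing-flap segments via a harmonic-ratio statistic derived from the
    normalized autocorrelation, a 70-feature harmonic/spectral/temporal
    descriptor set (MFCCs with delta and delta-delta coefficients, three
    independent wingbeat-fundamental estimators, band-power ratios and
    spectral shape descriptors), a family-genus-species hierarchical
    classifier cascade with subject-grouped splitting, and explainable
    per-feature Shapley attributions validated against exact enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    xgboost,
    ranger,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, Software
RoxygenNote: 7.3.3
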