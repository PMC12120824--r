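Package: msibatch
Title: Batch-Effect Evaluation and Correction for Mass-Spectrometry-Imaging Feature Tables
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality-control-standard (QCS) driven evaluation and correction of
    batch effects in MALDI mass-spectrometry-imaging feature tables. Provides a
    SummarizedExperiment-based feature-table container with strict CSV
    import/export, TIC and internal-standard normalization, intraday/interday
    coefficient-of-variation reporting with Kruskal-Wallis batch tests, robust
    outlier-slide detection and acquisition-drift profiling, native
    empirical-Bayes location-scale (ComBat-type) and wavelet/ICA (WaveICA-type)
    batch correction, PCA score-space proximity metrics and PLS-DA VIP feature
    robustness comparison, a synthetic batch-experiment generator with ground
    truth for method validation, and a two-part evaluation/correction pipeline
    with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sva,
    mixOmics,
    optparse
Config/testthat/edition: 3
biocViews: BatchEffect, QualityControl, MassSpectrometry, ImagingMassSpectrometry, Normalization
RoxygenNote: 7.3.3
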