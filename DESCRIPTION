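Package: eggpipe
Title: Gastric Myoelectric (EGG) Signal Analysis and Vagus Nerve
    Stimulation Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying the effect of electrical
    vagus nerve stimulation (VNS) on gastric myoelectric (electrogastrography,
    EGG) recordings. Provides a seeded synthetic EGG generator with realistic
    slow waves, artifacts and condition effects; artifact-robust
    pre-processing built on index-blocked discrete cosine transform band-pass
    filtering with per-window removed-sample bookkeeping; a battery of 27
    time- and frequency-domain window features (entropies, fractal dimension,
    Hjorth parameters, Welch spectral descriptors); an ensemble voting
    feature-selection algorithm over nine base selectors; and a
    permutation-test evaluation of cross-validated classifier performance
    using the two-sample Kolmogorov-Smirnov statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest,
    e1071,
    glmnet,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
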