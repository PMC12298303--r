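Package: edadecomp
Title: Phasic/Tonic Decomposition of Electrodermal Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for decomposing wearable electrodermal activity (EDA)
    recordings into a slow tonic (skin conductance level, SCL) component and
    a fast phasic (skin conductance response, SCR) component. Provides
    standard preprocessing (Butterworth low-pass cleaning, non-overlapping
    3-minute framing, resampling), a physiologically grounded synthetic-EDA
    generator built on Bateman-shaped impulse responses with ground-truth
    components, robust Theil-Sen detrending, an unsupervised
    non-autoregressive transformer decomposer with autocorrelation attention
    and a weight-free average-pooling tonic branch, and an evaluation suite
    (tonic-slope direction binning, SCR peak statistics, Kullback-Leibler
    and Jensen-Shannon histogram comparisons) for comparing decomposition
    methods without ground-truth labels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
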