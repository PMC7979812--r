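Package: readscan
Title: Reading Eye-Movement Profiling and Scanpath Similarity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for building a comprehensive eye-movement profile of
    multi-line paragraph reading from fixation/saccade/blink event streams:
    event cleaning (interest-period trimming, fixation merging, blink-adjacent
    removal), word-based interest-area mapping with vertical drift correction,
    global and local reading metrics (first-pass segmentation, dwell times,
    skipping, regressions), a saccade taxonomy separating return-sweeps,
    undersweeps and reading-atypical directional deviations, duration-weighted
    scanpath dissimilarity (Scasim) with non-metric MDS embedding and
    BIC-selected clustering, and a group-comparison layer (unbiased Hedges' g
    with exact noncentral-t confidence intervals, JZS Bayes factors,
    percentage-bend correlations, gamma GLMM design construction). Includes a
    synthetic two-group scanpath simulator so the full pipeline can be
    exercised end-to-end without proprietary stimulus texts.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    mclust,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
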