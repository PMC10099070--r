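Package: reachnet
Title: Source-Level EEG Spectral Perturbation and Directed Connectivity
    During Reaching Preparation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for source-level EEG analysis of
    reaching-movement preparation: event-related spectral perturbation
    (ERSP) via complex Morlet continuous wavelet transform, pairwise
    spectral Granger causality (Geweke decomposition of a bivariate
    vector-autoregressive model) between cortical regions of interest,
    weighted directed-graph in/out-degree centralities, and the group
    statistical layer (Wilcoxon signed-rank with Benjamini-Hochberg FDR,
    paired sign-flip permutation tests, 1-D cluster permutation tests).
    Includes a synthetic-data generator producing multi-subject
    multi-trial ROI time series from stable VAR processes with programmed
    band-limited amplitude envelopes, evoked transients and 1/f noise,
    together with the analytic spectral-GC oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
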