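Package: netsig
Title: Spectral and Network-Topology Signatures of Resting-State EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantitative EEG pipeline for resting-state scalp
    recordings: deterministic preprocessing (common average reference, FIR
    band-pass and notch filtering, epoch selection), Welch power spectral
    density with relative band power and aperiodic (1/f) exponent and offset,
    weighted phase lag index (wPLI) functional connectivity, binarized
    graph-theory network metrics (clustering, path length, global efficiency,
    betweenness, modularity, small-world index), permutation and split-plot
    ANOVA group statistics with Benjamini-Hochberg correction, and
    cross-validated logistic classification comparing clinical-only against
    clinical-plus-qEEG models. Includes a fully seeded synthetic multichannel
    EEG cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car,
    withr,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
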