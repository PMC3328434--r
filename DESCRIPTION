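Package: ffpeqc
Title: Quality-Aware Expression Profiling of FFPE Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quality-aware gene expression analysis of
    formalin-fixed paraffin-embedded (FFPE) tissue profiled with
    probe-based microarrays. Implements per-sample RNA quality scoring
    from qPCR (Ct_diff), RNA-yield and array quality gates,
    negative-control detection calls, monotone spline quantile
    normalization, a per-gene quality-sensitivity screen, probe sequence
    composition analysis, quality-matched differential expression with
    Benjamini-Hochberg correction, Pearson-correlation hierarchical
    clustering, and delta-delta-Ct qPCR validation, together with a
    synthetic FFPE degradation simulator that provides ground truth for
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    broom,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
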