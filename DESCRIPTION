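Package: spoarcnet
Title: Spatialization of Verbal Serial Order in Working Memory: Behavioral
    Moderation and Brain-Network Modularity Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the SPoARC (Spatial Position Association of
    Response Codes) effect at the level of individual differences. Provides a
    fully seeded synthetic-data generator for item-probe reaction-time trials,
    attention and working-memory task batteries, and multi-run node time series
    with planted community structure; reaction-time trimming and
    binomial-guessing exclusion rules; the per-participant SPoARC magnitude
    (right-hand minus left-hand slope of RT on serial position); multilevel
    mixed-effects moderation models with cross-level interactions,
    Johnson-Neyman regions of significance and pick-a-point simple slopes;
    a functional-connectivity network pipeline (correlation, run averaging,
    density thresholding and binarization, Newman-style modularity
    maximization); and dependent-correlation (Steiger) comparisons of
    brain-behavior correlations across network scales.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
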