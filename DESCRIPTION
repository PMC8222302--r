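Package: pniscore
Title: Expression Profiling and a Percentile Gene-Score Panel for Perineural
    Invasion in Cutaneous Squamous Cell Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for NanoString nCounter-style expression analysis of head
    and neck cutaneous squamous cell carcinoma cohorts stratified by
    perineural invasion (PNI). Implements the full analysis chain as reusable
    functions: negative-control background correction, positive-control and
    housekeeping (CodeSet content) normalization, empirical-Bayes moderated
    t-statistics with Benjamini-Hochberg adjustment, fold-change filtering
    and DEG set comparison, gene-scaled Euclidean hierarchical clustering,
    a percentile-threshold gene-panel risk score with sensitivity,
    specificity and ROC/AUC evaluation, hypergeometric over-representation
    analysis against GMT gene sets, and cohort contingency/t-test summaries.
    A synthetic-cohort generator with planted fold changes and known lane
    factors makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
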