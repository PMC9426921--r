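Package: tfstrata
Title: Ontology-Stratified Ranking of Dominant Transcription Factors from
    Open Chromatin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks transcription factors (TFs) by their functional dominance
    in a set of accessible chromatin regions (ATAC-seq or DNase-seq peaks).
    Candidate TF binding-site tracks are stratified by the top enriched
    ontology terms of the query (GREAT-style binomial and hypergeometric
    tests over basal-plus-extension gene regulatory domains), per-term TF
    enrichment is thresholded with an adaptive p-value leap rule, and TFs
    are scored with a nonparametric rank-based statistic whose exact null
    distribution is computed by dynamic programming. Includes a differential
    mode for contrasting two samples, an abundance-only binomial-fold
    baseline, a robustness grid, and a synthetic fixture generator so the
    whole pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    data.table,
    withr,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
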