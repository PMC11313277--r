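Package: strataTx
Title: Sex-Stratified Differential Expression, Pre-Ranked Pathway
    Enrichment, and Literature Impact Scoring for Bulk RNA-Seq
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A stratified bulk RNA-seq analysis pipeline for case/control
    cohorts split by a grouping variable such as biological sex. Provides
    covariate variance partitioning as a pre-test gene filter, negative
    binomial Wald differential expression adjusting for Age, RNA integrity
    (RIN) and post-mortem interval (PMI), pre-ranked gene-set enrichment
    on the -log10(p) x log2-fold-change statistic with a gene-sampling
    permutation null, cross-stratum pathway comparison, and a literature
    Impact Z-score that measures how strongly each enriched pathway
    co-occurs with a disease term in a bibliographic corpus relative to a
    null of randomly sampled pathways. A negative binomial cohort
    simulator with planted diagnosis effects makes every stage testable
    without access to controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    fgsea,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
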