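Package: her2lead
Title: HER2-Stratified Differential Expression and Leading-Edge Gene
    Frequency Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for biomarker-stratified transcriptomic analysis of
    tumour cohorts. Samples are assigned HER2 status either from ordinal
    immunohistochemistry scores (score >= 2+ positive) or by comparing
    ERBB2 mRNA expression with the cohort mean. Differential expression
    between the resulting groups uses median-of-ratios library-size
    normalization and a negative-binomial Wald test with
    method-of-moments dispersion, followed by the study filters (minimum
    normalized count, two-fold change, nominal p < 0.05). Gene set
    enrichment analysis is implemented as the weighted Kolmogorov-Smirnov
    running-sum statistic with gene-set or phenotype permutation
    p-values and leading-edge gene extraction; genes are then ranked by
    their frequency across the leading edges of significant pathways,
    and two cohorts can be compared for shared pathways and top genes.
    A microarray arm filters probes by MAS5 presence and GCRMA
    coefficient of variation and collapses probes to genes by maximum
    expression. A synthetic-data module generates negative-binomial count
    matrices, probe-level array pairs, gene-set collections with planted
    enrichment, and cohort metadata, so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
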