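Package: bminet
Title: System-Level Co-Expression Network Analysis of BMI-Associated Gene
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for system-level analysis of gene
    expression in relation to body mass index (BMI): quantile
    normalization and empirical-Bayes batch adjustment, stratum-median
    weight-group assignment, moderated two-group differential expression
    with pi0 / q-value estimation, weighted gene co-expression networks
    (soft thresholding, unsigned topological overlap, module detection
    and merging, module-trait statistics), percentile-thresholded
    differential connectivity with hub-conversion calls, information-
    theoretic three-way (synergy) interaction detection, and
    hypergeometric gene-set over-representation. Ships a synthetic-cohort
    generator that plants modules, trait-coupled eigengenes, group-specific
    hub genes and XOR-style synergy triples, so every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    withr,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva,
    jsonlite
Config/testthat/edition: 3
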