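Package: mirhcc
Title: Integrative miRNA Expression Meta-Analysis and Target-Disease Gene
    Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for relating a microRNA to a disease
    from heterogeneous evidence streams: random-effects meta-analysis of
    two-group expression summary statistics (Hedges' g, DerSimonian-Laird
    tau-squared, Cochran's Q and I-squared, leave-one-out sensitivity),
    hypergeometric co-citation scoring of gene-disease association from
    document mention tables, consensus miRNA-target calling by support
    voting across prediction tools, hypergeometric gene-set and pathway
    enrichment, degree-based hub-gene detection in typed interaction
    networks, and the final intersection of predicted targets with
    literature-derived disease genes. A synthetic-data module generates
    every pipeline input with known ground truth so all stages are
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
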