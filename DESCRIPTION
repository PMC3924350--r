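Package: miRcoNet
Title: Integrative miRNA-mRNA Differential Expression and Coexpression
    Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrative analysis of paired miRNA and mRNA
    expression profiles from two-group designs: empirical-Bayes moderated
    differential expression with Benjamini-Hochberg control, construction of
    a consensus miRNA-mRNA interaction universe from multi-tool target
    predictions and validated interactions, positively and negatively
    correlated bipartite targeting networks with randomized null controls and
    per-miRNA/per-mRNA hypergeometric over-targeting tests, Monte Carlo
    cross-species overlap tests on miRNA families and homologous gene sets,
    and a signed weighted gene coexpression analysis (soft-threshold
    adjacency, topological overlap, module detection, eigengenes,
    module-trait statistics, hub networks). A synthetic-data generator
    emulates the statistical structure of such studies so every stage can be
    exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
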