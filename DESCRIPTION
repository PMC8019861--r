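Package: netprio
Title: Network-Based Drug-Target Prioritization from Differential
    Expression and Protein Interaction Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for prioritizing drug
    targets from two-group gene expression data and a protein-protein
    interaction (PPI) interactome. Differentially expressed genes are
    called by per-gene one-way ANOVA (with cross-platform minimum-p
    merging) or by a median-split Fisher exact test with
    Benjamini-Hochberg correction, projected onto the interactome to form
    a query-query PPI (QQPPI) network, and ranked by five graph
    centrality measures (degree, betweenness, closeness, eigenvector,
    centroid value). Proteins in the top-k of at least two measures form
    a consensus set that is joined against a drug-target table to yield
    prioritized drug-target pairs. Includes a seeded synthetic-study
    generator (scale-free interactome with planted hubs, two-group
    expression with planted effects, degree-biased drug table) so the
    whole pipeline is testable without any external download, plus a
    PSI-MITAB 2.5 reader for real interactome data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
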