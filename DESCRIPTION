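Package: fibronet
Title: Multi-Omics Correlation Networks for Time-Course Fibrosis Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of time-course transcriptomics,
    metabolomics and lung-function phenotypes in experimental pulmonary
    fibrosis. Provides per-time-point differential analysis for genes and
    metabolites (with detection-limit-aware missingness filtering and
    per-time-point k-nearest-neighbour imputation), construction of gene
    co-expression and metabolite correlation networks from FDR-filtered
    Spearman correlations, Leiden community detection with size-ordered
    subnetwork labels and clustering-coefficient summaries, phenotype-node
    centrality, hypergeometric over-representation against gene-set and
    metabolic-subsystem annotations, subsystem-based bridging of gene and
    metabolite subnetworks, cross-species concordance of differential
    signatures through ortholog maps, and scoring of perturbation-induced
    reversal of disease-dysregulated subnetworks. A seeded synthetic-data
    generator with planted co-expression modules, trajectories, phenotype
    couplings and abundance-dependent missingness supports ground-truth
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
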