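Package: antennaSeq
Title: Receptor-Repertoire Classification and Genotype Survival Analysis of
    Antennal Single-Nucleus RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying odorant-receptor-neuron (ORN) survival in
    insect antennae from single-nucleus and bulk RNA-seq. Implements
    two-stage cell QC, CP10k/log1p normalisation, batch-aware highly
    variable gene selection, PCA, exact kNN graphs and Leiden clustering;
    per-cell receptor "expressing" calls by a one-sided Mann-Whitney test
    of the focal cell's graph neighborhood against a fixed background of
    wild-type nonneuronal cells; rule-based receptor-combination cell
    categories with wild-type versus co-receptor-mutant survival tallies;
    bulk developmental trajectory summaries and PC-loading-derived stage
    gene sets; identification of odorant-receptor genes retained in
    co-receptor mutants by cross-platform fold-change concordance with
    neighbor-gene coexpression scoring; and synteny-aware reciprocal
    best-hit transfer of tandem-cluster gene identifiers between genome
    assemblies. A synthetic-data module generates ground-truth-labelled
    datasets with the statistical structure the analysis assumes, so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    igraph,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    SingleCellExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, GeneExpression, QualityControl,
    Clustering, Annotation
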