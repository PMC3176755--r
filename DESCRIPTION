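Package: MMCarray
Title: Probe-Level Microarray Analysis of Rare Plant Cell Types with
    Negative-Probe Detection Calls
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing Affymetrix-style probe-level expression data
    from laser-microdissected plant cell types, modelled on the analysis of the
    Arabidopsis megaspore mother cell (MMC) transcriptome. Implements probe
    re-annotation against transcript and genomic sequence (substitution-only
    mismatch search), selection of non-matching negative probes, RMA and
    model-based (Li-Wong type) expression summarization, empirical
    present/marginal/absent detection calls from a resampled negative-probeset
    null (PANP-style), empirical-Bayes moderated t/F enrichment analysis across
    a tissue atlas, Fisher-based gene-set and GO-graph enrichment with elim and
    weight decorrelation, hierarchical clustering utilities, and transmission
    genetics statistics for reciprocal crosses. A synthetic-data generator with
    known ground truth makes every stage testable without external array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment,
    limma,
    igraph,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Microarray, Preprocessing, DifferentialExpression,
    GeneSetEnrichment, Clustering
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotation.R'
    'clustering.R'
    'detection.R'
    'enrichment.R'
    'genetics.R'
    'setenrich.R'
    'simulate.R'
    'summarize.R'
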