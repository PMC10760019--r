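Package: retroregulon
Title: Transposable-Element-Centric Multi-Omic Analysis of Bulk
    Transcriptomes and Chromatin Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint quantification of gene and transposable-element (TE)
    expression from ambiguous read classes by expectation-maximization,
    TPM normalization and family-level aggregation, rank-based
    differential expression and cluster-marker detection, PCA/KNN-graph
    community clustering of samples, TE-family chromatin-accessibility
    enrichment against a size-matched random null, calling of putative
    cis-regulatory TE-gene pairs from paired ATAC-seq and RNA-seq
    contrasts, and a KRAB zinc-finger (KZNF) versus TE-family
    anticorrelation screen.  Includes a synthetic-data generator that
    emulates the statistical structure of such studies (negative-binomial
    counts with planted differential features and cluster structure,
    multi-mapping read ambiguity, planted accessible TE loci linked to
    nearby genes, latent-factor KZNF-TE coupling) together with the
    planted ground truth needed for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    igraph,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
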