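Package: haustorstage
Title: Stage Markers and Reference Genes for Haustorium Development Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for turning a staged multi-sample expression experiment into
    validated reference (housekeeping) genes, stage-specific marker genes, and a
    marker-based stage classifier for new samples. Implements count
    normalization (CPM, RPKM, TMM scaling factors), negative-binomial exact-test
    differential expression with common qCML dispersion, two-dimensional
    complete-linkage clustering of z-scored profiles, hypergeometric functional
    enrichment, gene-significance (trait-indicator correlation) statistics,
    multi-criteria housekeeper and marker selection, from-scratch geNorm,
    NormFinder and BestKeeper reference-gene stability scoring with
    geometric-mean rank integration, RT-qPCR relative quantification and
    reference normalization, and a negative-binomial synthetic-data generator
    with planted ground truth for end-to-end validation. Developed around the
    four-stage (niS, SWE, ATT, PEN) haustorium development design of the
    parasitic plant Cuscuta campestris, but applicable to other small staged
    designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
biocViews: Transcriptomics, DifferentialExpression, GeneExpression,
    Normalization, Clustering, qPCR
RoxygenNote: 7.3.3
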