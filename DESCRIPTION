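Package: trfscape
Title: Discovery, Classification and Screening of tRNA-Derived Fragments
    from Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying tRNA-derived fragments (tRFs) in small
    RNA sequencing data. Builds a mature-tRNA search space (intron removal,
    CCA addition, 50-nt genomic trailer), filters and places reads through a
    hierarchical decoy chain, assigns each fragment to one of the six
    positional tRF classes (tRF-5, tRF-3, tRF-1, i-tRF, 5'-half, 3'-half),
    screens tRF count time courses for differential expression with a
    negative-binomial test, and predicts miRNA-like tRF target sites in
    3'-UTRs by seed matching and intermolecular duplex minimum-free-energy
    scanning. A synthetic-data module generates all pipeline inputs with
    ground-truth labels for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
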