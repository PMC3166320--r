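Package: katzRank
Title: Katz-Centrality Based Prioritization of Candidate Disease Genes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Ranks candidate disease genes at mapped loci by propagating a
    differential-expression activity signal over a weighted protein-protein
    interaction network with a Katz-style score s = (I - phi*W)^-1 (d + eta*x),
    optionally seeded with known disease genes. Includes rank-based activity
    computation from case/control expression matrices, a Jacobi solver with a
    spectral-radius bound on phi, locus-based candidate set construction,
    r-ratio and ROC evaluation with parameter calibration, leave-one-out
    known-gene assessment, hypergeometric over-representation tests, and
    seeded synthetic benchmark generators (planted disease modules,
    randomization controls) so the full pipeline runs without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    yaml
biocViews: GraphAndNetwork, NetworkInference, GeneExpression,
    DifferentialExpression, SystemsBiology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
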