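Package: bindexnet
Title: Drug-Target Bipartite Networks and B-Index Similarity from
    Pharmacogenomic Cell-Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds bipartite drug-gene association networks by correlating
    standardized drug-activity profiles with gene-expression profiles across
    a cancer cell-line panel, with Holm family-wise error control and
    CellMiner-style retention thresholds. Quantifies drug-drug similarity
    from shared gene targets using the B-index, a size-adjusted set-overlap
    coefficient, alongside the Jaccard, Sorensen-Dice and Russell-Rao
    indices; clusters drugs by Ward.D2 agglomeration with inertia-based
    selection of the cluster count; and cross-validates pharmacogenomic
    clusters against chemical structural similarity (path-based fingerprint
    Tanimoto and maximum-common-substructure coefficients) computed from
    SMILES. Includes a seeded synthetic-panel generator with planted
    drug-gene correlations and planted drug families so the full pipeline
    is testable without access to the real screening data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    yaml,
    mclust,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ape
Config/testthat/edition: 3
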