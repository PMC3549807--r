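Package: MetNetPhylo
Title: Phyletic Tree Reconstruction by Global Alignment of Multiple
    Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs phyletic trees for sets of organisms from their
    metabolic networks. Cross-species node similarities are computed by an
    IsoRank-style power iteration blending a sequence-similarity prior with
    network topology; a star-alignment procedure with personalized PageRank
    extracts multi-species enzyme clusters; clusters are filtered by the
    Shannon entropy of their KEGG group annotations; cluster co-membership
    yields a Jaccard organism distance matrix from which a neighbor-joining
    tree is built. Includes per-pathway shared-enzyme statistics, PHYLIP and
    Newick interoperability, and a synthetic-network evolution simulator with
    planted orthology for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
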