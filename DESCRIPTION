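Package: jenscape
Title: Comparative Genomics of Yeast Carboxylate Transporter Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for delimiting a transporter gene family
    across yeast proteomes and reconstructing its evolutionary history:
    reciprocal-best-hit homolog screening built on affine-gap local alignment
    with Karlin-Altschul E-values, progressive multiple alignment with
    conserved-block filtering, distance-based phylogeny (Neighbor-Joining and
    BioNJ) with bootstrap support and outgroup rooting, duplication-loss
    parsimony reconciliation of gene trees against a species tree, degenerate
    transporter-motif scanning, and substrate consumption-rate estimation
    from concentration time series. Includes seeded simulators for gene-family
    birth-death evolution along a species tree, sequence evolution, decoy
    proteomes, and noisy consumption curves, so every stage can be validated
    against recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
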