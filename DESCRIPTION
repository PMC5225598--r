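Package: pocketmotif
Title: Classification of RNA-Binding Pockets by Structure-Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies structural motifs of protein-RNA recognition from
    binding pockets on protein surfaces. Provides non-sequential-order rigid-body
    alignment of residue pockets with a Q-score similarity measure, empirical
    significance calibration against a background of random pocket pairs via a
    generalized extreme value fit, construction of pocket (and protein)
    similarity networks with greedy modularity community detection, consensus
    multiple structure alignment by maximum-weight matching, per-column motif
    profiles with RNA-binding-residue ratios, and hypergeometric / EASE term
    enrichment. A synthetic-data generator produces pocket families, background
    pockets and toy protein-RNA complexes with ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
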