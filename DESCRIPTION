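Package: markerprobe
Title: Marker-Gene Proxies for Viral Gene Content and Amplicon Community Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Validates a conserved marker gene (the T4-like phage DNA polymerase
    gp43) as a proxy for whole-genome gene content in cyanomyoviruses, and turns
    marker-gene amplicon sequencing into community ecology results. Implements
    gene-content phylogenetic distance from protein-cluster presence/absence,
    neighbor-joining tree construction, Mantel permutation tests of distance-matrix
    congruence, amplicon clustering-threshold calibration, a paired-end amplicon
    pipeline (quality trimming, pair merging, translation, dereplication, greedy
    amino-acid-identity OTU clustering, chimera and reference screens, clade
    assignment), community statistics (rarefaction, Shannon alpha/beta diversity,
    PCoA, ANOSIM, canonical correspondence analysis with permutation-based forward
    selection, indicator-species IndVal statistics), and a synthetic-data generator
    that produces every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    generics,
    methods,
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
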