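Package: dheqtl
Title: Expression QTL Mapping in Doubled-Haploid Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end expression QTL (eQTL) analysis pipeline for
    biparental doubled-haploid (DH) populations: marker filtering and bin
    division, Kosambi genetic-map construction over the physical marker
    order, Haley-Knott interval mapping with forward-selected cofactors
    (composite interval mapping) and permutation-based genome-wide LOD
    thresholds, cis/trans classification of eQTLs, sliding-window
    trans-eQTL hotspot detection, a matched-resampling null for enrichment
    of eQTL-eGene pairs in 3D-genome interaction anchors, and candidate-gene
    prioritization by intersection of interval membership, cis-eQTL status
    and trait-expression correlation across microenvironments. Includes a
    synthetic-data generator that plants known cis/trans architecture,
    master-regulator hotspots and pleiotropic trait loci for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
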