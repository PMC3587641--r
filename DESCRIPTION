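Package: ltrtrace
Title: Structural Annotation and Classification of LTR-Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico workbench for detecting, reconstructing and
    structurally annotating LTR-retrotransposons (Copia, Gypsy and Gmr1-like
    lineages) in crustacean-style sequence data. Provides degenerate-primer
    in-silico PCR, divergence-based family clustering, overlap-validated
    chimeric consensus assembly, structural annotation (LTR pair, primer
    binding site, polypurine tract, ORFs with defect reporting, protein
    domain motifs and superfamily calls from pol domain order), a
    Karlin-Altschul ranked similarity classifier implementing the
    two-condition GalEa clade rule, and distance phylogenetics (JTT+Gamma
    pairwise distances, neighbor joining, nonparametric bootstrap). A fully
    seeded synthetic-data generator plants ground-truthed elements so every
    stage is verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    phangorn,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
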