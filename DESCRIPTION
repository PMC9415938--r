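Package: catyper
Title: Genome-Based Typing of Cyanobacterial Chromatic Acclimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the chromatic acclimation (CA) capability of
    cyanobacteria from annotated genome content. Classifies GAF-domain
    photoreceptors (CcaS, RcaE, RfpA) by reference similarity, domain
    architecture and diagnostic residues; reannotates phycobilisome linker
    proteins (CpcG vs CpcL by a C-terminal hydrophobic-helix test, canonical
    vs far-red ApcE by linker-repeat count and chromophore-cysteine
    presence); detects the far-red light photoacclimation (FaRLiP) gene
    cluster by synteny; verifies phycoerythrobilin synthesis capability; and
    combines the evidence into per-genome CA-type calls (CA1-CA3, CA6, CA7).
    Includes neighbor-joining phylogenetics with maximum-likelihood JTT
    distances and bootstrap support, and a synthetic-genome generator
    providing ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    ape,
    dplyr,
    generics,
    ggplot2,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    withr
Suggests:
    Matrix,
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
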