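Package: cas13scout
Title: Mining Metagenomic Contigs for Novel Cas13 (Type VI CRISPR) Effectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of a metagenomic Cas13-discovery
    pipeline. Detects CRISPR arrays in assembled contigs with a seed-and-extend
    repeat finder, extracts 20 kb flanking regions, calls and translates open
    reading frames under the bacterial genetic code, screens proteins longer
    than 400 residues against a profile-HMM library of Cas13 family alignments,
    enforces the dual-HEPN (R-X4-H motif) completeness filter, classifies
    surviving candidates into known or novel subtypes by UPGMA on pairwise
    global-alignment identity, characterises direct-repeat and spacer features
    (consensus, conservation, Nussinov base-pair-maximisation secondary
    structure), matches spacers to a target database, and predicts the
    functional crRNA direct-repeat orientation from the presence of an
    elongated N-terminal domain. A deterministic synthetic-locus generator with
    machine-readable ground truth supports testing end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    yaml,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
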