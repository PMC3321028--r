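Package: nlrscan
Title: Genome-Wide Annotation of NBS-LRR Resistance Gene Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for annotating the NBS-LRR (NLR) disease
    resistance gene complement of a plant genome assembly. Builds and
    iteratively refines profile hidden Markov models of the NB-ARC domain with
    empirical Gumbel E-value calibration and protein-kinase exclusion;
    classifies candidates into the eight canonical domain architectures (CNL,
    CN, NL, N and their TIR-lineage counterparts) from coiled-coil, TIR and
    LRR motif scans plus the kinase-2 NBS signature; anchors genes to
    pseudomolecules and detects physical clusters, super-clusters and
    singletons; recovers NBS-derived genes from flanking windows; calls
    pseudogenes with a frameshift-aware protein-to-DNA alignment that labels
    the disabling lesion; and reconstructs a neighbor-joining phylogeny of
    P-loop-anchored NBS domains with bootstrap support and CC(I)/CC(II)/TIR
    clade assignment. A synthetic-genome generator plants NLR genes,
    pseudogenes, kinase decoys and background genes with full ground truth so
    every stage is testable without a reference assembly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
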