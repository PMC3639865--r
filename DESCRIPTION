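Package: hlatyper
Title: Automated Amplicon Sequencing Workflow for HLA Class I and II Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of an automated amplicon
    next-generation-sequencing workflow for HLA class I and class II
    genotyping: an annotated allele reference database with an
    exon/intron-aware FASTA dialect, a 17-amplicon fusion-primer panel model
    with multiplex identifiers (MIDs) and pooling factors, library-preparation
    computations (standard-curve quantification, molarity conversion,
    two-pool equimolar plans), a pyrosequencing-style read simulator with
    substitution and homopolymer error models, exact-match demultiplexing and
    exon-boundary trimming, a layered read-to-allele genotype caller with
    4-digit ambiguity strings, intron-based null-allele exclusion, phase-layer
    mismatch accounting, and phased-versus-unphased ambiguity-reduction
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
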