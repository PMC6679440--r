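Package: amplisnv
Title: Position-Specific Background Error Modelling and Low-Frequency SNV
    Calling for Amplicon Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects single nucleotide variants at low allele fractions in
    amplicon-based deep sequencing data (for example Ion AmpliSeq liquid
    biopsy panels). A cohort of normal samples is used to estimate a
    position-, alternative-allele- and strand-specific background
    sequencing error rate with an additive pseudo-count; candidate
    variants in tumour samples are then scored against this model with a
    cumulative Poisson tail test per strand, converted to Phred-scaled
    quality scores, and annotated with quality flags (low quality, low
    supporting reads, amplicon edge, strand bias, homopolymer context,
    high-noise position). Includes a simulator for synthetic normal
    cohorts and spike-in variants, benchmark drivers for self-consistency
    and sensitivity experiments, and standard confusion-matrix
    performance measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
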