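Package: splicegain
Title: Discovery and Consequence Analysis of Splice-Site-Creating Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies single-nucleotide variants that create canonical
    splice-site dinucleotides (GT donors, AG acceptors) near annotated
    exon-intron boundaries, derives the resulting novel junctions (exon
    extensions and shrinkages), classifies their functional consequences
    (premature termination codons, frameshifts, predicted nonsense-mediated
    decay, protein-domain disruption), validates calls against splice-junction
    read evidence via the junction allele fraction, summarises positional and
    mutational spectra of such mutations, and screens family cohorts for rare
    recessive candidates. Includes a seeded synthetic-data generator that
    emulates a multi-gene genome with planted mutations and known ground
    truth so the full pipeline is testable end to end.
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
    GenomicAlignments,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
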