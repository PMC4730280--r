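Package: sodsplice
Title: Alternative Splicing, Isoform Enumeration and Expression Analysis of
    Fungal Superoxide Dismutase Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for studying superoxide dismutase (SOD) gene
    families in fungal genomes: identification of SOD candidates in a proteome by
    exact Smith-Waterman local alignment with Karlin-Altschul e-values and
    conserved metal-binding residue profiles; junction-aware mapping of paired-end
    transcriptome reads to gene regions; GT-AG splice-junction calling and
    classification of alternative-splicing modes (intron retention, alternative
    5'/3' splice sites); combinatorial transcript isoform enumeration with ORF
    detection, translation and domain screening, including start codons located
    inside retainable introns; neighbor-joining phylogeny from p-distances under
    partial deletion with bootstrap support; and 2^-ddCt RT-qPCR relative
    expression with LSD compact-letter displays and Pearson correlations. A
    synthetic-data module generates gene fixtures with configurable intron
    layouts, isoform mixtures, paired-end reads and replicate Ct tables so every
    stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
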