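Package: hybriddyn
Title: Genome Dynamics of Laboratory-Evolved Interspecies Yeast Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and classification of the genomic changes that arise
    when allodiploid interspecies yeast hybrids are propagated for many
    generations: SNP and INDEL calling with parent-strain subtraction,
    read-coverage copy-number segmentation for whole-chromosome and
    segmental aneuploidy, loss-of-heterozygosity recombination calling,
    mitochondrial-genome loss classification, chimeric open-reading-frame
    breakpoint reconstruction from local assembly, and per-cell-division
    mutation-rate estimation. Includes a synthetic allodiploid evolution
    simulator (two-subgenome genomes with homeologous ORF pairs, injected
    evolution events with a replayable truth ledger, and paired-end read
    simulation) so that every stage of the pipeline is testable at desk
    scale, plus flow-cytometric genome-size estimation and off-gas CO2
    growth-rate estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
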