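Package: phageCPA
Title: Characterization of Fast-Propagating White-Plaque Clones in M13KE
    Phage Display Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize propagation-related target-unrelated
    peptides (Pr-TUPs) arising in M13KE-based phage display libraries such
    as Ph.D.-7. Implements extraction and filtering of NNK-encoded 7-mer
    displayed peptides from single-end amplicon FASTQ reads, competitive
    propagation assay summaries from plaque counts and NGS peptide
    frequencies, provenance classification of white plaques via signature
    nucleotides distinguishing WT-M13KE from environmental WT-M13, calling
    and annotation of large genomic deletions from assembled genome pairs,
    phage quantitation arithmetic (qPCR genome copies, plaque titers,
    ELISA binding ratios), and a deterministic synthetic-data generator
    emulating the assay so every stage is testable without raw sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
biocViews: Sequencing, Software, SequenceMatching
RoxygenNote: 7.3.3
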