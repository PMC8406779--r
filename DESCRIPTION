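Package: rnascout
Title: Profile-HMM Discovery of Divergent Non-Coding RNA Genes with
    Promoter, Terminator and Structure Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for finding divergent non-coding RNA gene family
    members in a genome when primary-sequence similarity is too weak for
    BLAST-style search. Builds a nucleotide profile hidden Markov model
    from a multiple alignment of known family members, scans both strands
    of a genome with local Viterbi alignment, and filters hits by a
    two-end model-coverage rule. Candidate loci are then vetted with the
    Drosophila snRNA promoter grammar (PSE/TATA/PSEB elements and their
    spacing, including the TC dinucleotide diagnostic of RNA polymerase
    III specificity), scanned for oligo-T RNA polymerase III terminators,
    folded with a Nussinov-style secondary-structure model to verify
    conserved hairpin motifs, and supported by in-silico PCR and
    semi-quantitative RT-PCR dilution normalisation utilities. A
    ground-truthed synthetic-genome generator allows end-to-end recovery
    experiments with known implants.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
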