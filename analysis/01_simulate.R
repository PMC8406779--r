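#!/usr/bin/env Rscript
# Stage 1 — simulate the study system.
#
# Builds the canonical synthetic locus (PSE -8bp- TATA -18bp- TSS, a
# 404-bp gene with five internal T4-T5 tracks and a 4+6 double-T
# terminator, five designed hairpin motifs, complementary termini), a
# divergent 8-member family derived from the gene to train the profile
# HMM, and a 2.5-kb genome with the cassette implanted at a recorded
# position. Writes everything under results/.

suppressPackageStartupMessages(library(rnascout))

seed <- 42
set.seed(seed)
dir.create("results", showWarnings = FALSE)

cs <- make_cassette()
fam <- make_family(8, substitution_rate = 0.08, indel_rate = 0.01,
                   template = cs$gene_seq)
sg <- make_genome(list(cs), contig_len = 2500)

write_genome(sg, "results/genome.fa", "results/truth.gff3")
writeLines(paste0(">", names(fam$sequences), "\n", fam$sequences),
           "results/family.afa")
jsonlite::write_json(
  list(seed = seed, tss_offset = cs$tss_offset,
       gene_length = nchar(cs$gene_seq),
       primers = as.list(cs$primers),
       motifs = cs$motifs,
       internal_t_tracks = cs$internal_t_tracks,
       truth = sg$truth),
  "results/simulation.json", auto_unbox = TRUE, digits = NA)

tss <- sg$truth[sg$truth$type == "TSS", ]
cat(sprintf(
  "Simulated %d-bp genome (seed %d): cassette on %s, TSS at %s:%d(%s)\n",
  nchar(sg$sequences[[1]]), seed, tss$contig, tss$contig, tss$start,
  tss$strand))
cat(sprintf(
  "Family: %d members, %d alignment columns, mean pairwise identity %.2f\n",
  length(fam$sequences), fam$length, {
    M <- do.call(rbind, strsplit(unname(fam$sequences), ""))
    mean(utils::combn(nrow(M), 2, function(p)
      mean(M[p[1], ] == M[p[2], ])))
  }))
cat("Wrote results/genome.fa, results/truth.gff3, results/family.afa,",
    "results/simulation.json\n")
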