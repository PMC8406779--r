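#!/usr/bin/env Rscript
# Stage 4 — secondary-structure verification of the candidate RNA.
#
# Folds the gene body with the built-in maximum-score folder, checks
# that the 5' and 3' ends pair into the closed core typical of 7SK
# RNAs, reads the GAUC/GAUG variant of the 5' stem, and verifies the
# annotated hairpin motifs (M1/M3/M8, stems A and B).

suppressPackageStartupMessages(library(rnascout))

gv <- jsonlite::read_json("results/gene_verdict.json",
                          simplifyVector = TRUE)
sim <- jsonlite::read_json("results/simulation.json",
                           simplifyVector = TRUE)

rna <- extract_downstream("results/genome.fa", gv$contig, gv$tss,
                          gv$strand, span = gv$gene_length)
st <- fold_rna(rna)
write_dotbracket(st, "results/structure.db", id = "candidate")
cat(sprintf("Folded %d nt: %d pairs, score %.0f\n", nchar(rna),
            nrow(st$pairs), st$score))

core <- check_core(st)
cat(sprintf("Core: closed=%s (%d end pairs), 5'-stem variant %s\n",
            core$closed, core$n_end_pairs, core$gauc_variant))

motifs <- verify_motifs(st, sim$motifs)
print(motifs[, c("name", "start", "end", "n_pairs_within", "verified")])

jsonlite::write_json(
  list(closed = core$closed, n_end_pairs = core$n_end_pairs,
       gauc_variant = core$gauc_variant, motifs = motifs),
  "results/structure_report.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/structure.db, results/structure_report.json\n")
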