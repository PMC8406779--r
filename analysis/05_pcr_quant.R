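#!/usr/bin/env Rscript
# Stage 5 — in-silico PCR and semi-quantitative RT-PCR arithmetic.
#
# Predicts the PU15/PU12 product on the candidate transcript (210 nt by
# construction), shows that a forward primer upstream of the TSS yields
# no product, and works a dilution-series example: expression of the
# candidate relative to a housekeeping reference, read at the
# reference's least saturated 5-fold dilution.

suppressPackageStartupMessages(library(rnascout))

gv <- jsonlite::read_json("results/gene_verdict.json",
                          simplifyVector = TRUE)
sim <- jsonlite::read_json("results/simulation.json",
                           simplifyVector = TRUE)
gene <- extract_downstream("results/genome.fa", gv$contig, gv$tss,
                           gv$strand, span = gv$gene_length)

amp <- find_amplicon(gene, sim$primers$PU15, sim$primers$PU12,
                     fwd_name = "PU15", rev_name = "PU12")
print(amp)
out <- data.frame(fwd = "PU15", rev = "PU12", start = amp$start,
                  end = amp$end, length = amp$length)
no_prod <- find_amplicon(gene, sim$primers$PU10, sim$primers$PU12)
cat(sprintf("PU10 (upstream of the TSS) x PU12: %s\n",
            if (is.null(no_prod)) "no product, as expected" else
              "unexpected product"))
utils::write.table(out, "results/amplicons.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# dilution ladder example: reference saturates until 5^8
csv <- "results/band_intensities.csv"
writeLines(c("sample,gene,exponent,intensity",
             "adult,rp49,6,1.00", "adult,rp49,7,0.95",
             "adult,rp49,8,0.40",
             "adult,7SK94F,6,0.30", "adult,7SK94F,7,0.10",
             "adult,7SK94F,8,0.02"), csv)
series <- read_band_intensities(csv)
r <- relative_expression(series$adult$`7SK94F`, series$adult$rp49)
cat(sprintf(
  "Least saturated rp49 dilution: 5^%d; 7SK94F/rp49 ratio there: %.3f\n",
  r$chosen_exponent, r$target_over_reference))
cat(sprintf(
  "Two samples read at 5^8 vs 5^6 with equal bands differ %gx in input\n",
  dilution_scale_factor(8, 6)))
utils::write.table(
  data.frame(target = "7SK94F", reference = "rp49",
             chosen_exponent = r$chosen_exponent,
             ratio = r$target_over_reference),
  "results/expression_ratios.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
cat("Wrote results/amplicons.tsv, results/expression_ratios.tsv\n")
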