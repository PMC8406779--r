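# rnascout

Discovery of divergent non-coding RNA genes when sequence similarity
alone is too weak to find them.

Regulatory RNAs such as the 7SK snRNA are conserved by structure and
function while their primary sequence drifts; across large
evolutionary distances BLAST finds nothing, yet the gene is still
recognisable by the *combination* of weak full-length homology, an
snRNA promoter with canonical element spacing, an RNA polymerase III
oligo-T terminator, and a folded architecture whose 5' and 3' ends
pair into a closed core. `rnascout` implements that composite search
as a tested R pipeline for people who need to hunt ncRNA family
members in annotated or draft genomes — and to know, on simulated
genomes with known implants, exactly how well each stage performs.

## What it computes

* **Profile HMM** (`build_profile`): per-column match emissions
  $e_j(x)$ with Laplace pseudocounts, $P(x\mid j) =
  (c_{jx}+1)/(n_j+4)$, M/I/D transitions, and background $q(x)$ from
  the training alignment.
* **Local scoring** (`viterbi_local`, `forward_local`): best and total
  log-odds $\log\!\big[P(\text{path})/\prod_i q(x_i)\big]$ over
  local–local paths (free entry/exit at any match column); bits in all
  reports; empty alignment scores 0. Verified against complete path
  enumeration.
* **Genome scan + two-end filter** (`scan_genome`,
  `two_end_filter`): windowed two-strand scanning; a hit survives only
  with strictly more than 100 bp aligned to *both* the 5' and the 3'
  region of the model — the rule that separates one full-length
  candidate from one-ended spurious hits.
* **Promoter grammar** (`annotate_promoter`,
  `classify_polymerase`): PSE/TATA/PSEB PWM detection, the canonical
  PSE –8bp– TATA –18bp– TSS spacing, and the TC dinucleotide at PSE
  positions 19–20 that marks Pol III-type snRNA promoters.
* **Terminators and gene model** (`find_t_tracks`,
  `build_gene_model`): maximal oligo-T runs, single/double terminator
  calls, inclusive gene length TSS→terminator, and a Pol III
  plausibility verdict from the internal track inventory.
* **Secondary structure** (`fold_rna`, `check_core`,
  `verify_motifs`): Nussinov-style maximum-score folding with stacking
  (scores, not free energies; verified against exhaustive structure
  enumeration), the closed 5'–3' core check, the GAUC/GAUG 5'-stem
  variant, and verification of annotated hairpin motifs (M1/M3/M8,
  stems A/B).
* **PCR utilities** (`find_amplicon`, `relative_expression`):
  in-silico amplicon prediction and semi-quantitative RT-PCR ratios
  read at the least saturated 5-fold dilution of a housekeeping
  reference.
* **Synthetic data** (`make_cassette`, `make_family`, `make_genome`):
  ground-truthed cassettes (promoter + 404-bp gene + 4+6 double-T
  terminator + designed hairpins), divergent training families, and
  genomes with recorded implants (FASTA + GFF3 truth).

## Worked example

The numbered scripts under `analysis/` run the whole study on
simulated data (`Rscript analysis/01_simulate.R` … `05_pcr_quant.R`).
Stage 2–3 output, verbatim:

```
Trained profile HMM: 404 match columns
Scan: 1 merged hit(s) above 30 bits
Two-end filter (>100 bp on each model end): 1 hit(s) survive
  ctg1:1114-1517(+)  467.8 bits  5'cov=142 bp  3'cov=142 bp
Refined TSS: ctg1:1114(+)
Promoter annotation:
  PSE: 46-66 (1.00) GTCACTTTCAGGAGTTGCTCG
  TATA: 75-82 (1.00) TATAAATG
  PSE-TATA spacer: 8  TATA-TSS gap: 18
  verdict: POL3_TYPE
Gene model ctg1:1114(+)
  terminator: DOUBLE T4+6 at gene position 404, length 404 bp
  internal T-tracks: 5 (5 of 4-5 T; 4 in first 100 nt)
  Pol III transcription plausible: FALSE
```

Reading: the HMM trained on a divergent 8-member family finds exactly
one locus resembling both model ends (142 bp of 5' and 3' coverage,
where spurious hits show one end only). Its promoter has the Pol
III-type grammar — PSE and TATA at the canonical 8/18 spacing, TC at
PSE positions 19–20 — yet the 404-bp gene body carries five internal
T4–T5 tracks, each an efficient Pol III termination signal, so the
locus cannot plausibly be a Pol III transcription unit: the hallmark
contradiction of this gene class. Stage 4 confirms the folded RNA
closes its 5'–3' core (14 end pairs) with the GAUG variant of the
HEXIM-contact stem and verifies all five annotated hairpins; stage 5
predicts the 210-nt PU15/PU12 product and no product from a forward
primer upstream of the TSS.

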