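---
title: "Finding divergent ncRNA genes: models, parameters and design choices"
author: "rnascout"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Finding divergent ncRNA genes}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rnascout)
```

## The problem

Abundant regulatory RNAs such as the 7SK snRNA are conserved by
*structure*, not by primary sequence. Across large evolutionary
distances the sequence drifts so far that BLAST-style searches fail,
while the promoter grammar, the RNA polymerase III termination signal,
and the folded architecture (a closed 5'–3' core, conserved hairpins)
remain recognisable. `rnascout` implements that composite search: a
profile hidden Markov model (HMM) finds weak full-length homology, and
a cascade of orthogonal signals — snRNA promoter elements and their
spacing, oligo-T terminators, secondary-structure motifs, in-silico PCR
— vets each candidate the way a curator would.

Everything is exercised against synthetic genomes with known implants,
so every number the pipeline reports can be compared with ground truth.

## The profile HMM

The family model is a classical nucleotide profile HMM with match (M),
insert (I) and delete (D) states per alignment column.

* **Match columns.** A column becomes a match state when its gap
  fraction is at most 0.5 (the common profile-construction heuristic);
  the threshold is a parameter of `build_profile()`.
* **Pseudocounts.** Emissions and transitions receive simple Laplace
  (+1 per symbol) pseudocounts rather than Dirichlet mixtures. This
  keeps every probability strictly positive and makes the estimator
  transparent: with three identical rows `ACGT`, the first-column
  emission of A is exactly $(3+1)/(3+4) = 4/7$. The pseudocount is
  configurable; raising it drives all emissions towards the background
  (a property the tests assert).
* **Background.** The pseudocounted overall residue frequency of the
  training alignment.
* **Local–local scoring.** Alignment is local in both the sequence and
  the model: entry is free into any match column, exit free from any
  match column, and flanking sequence is unscored. The empty alignment
  scores 0, so log-odds scores are never negative. Scores are natural
  log-odds internally and bits in every report. `N` emits at
  background, contributing 0.
* **Reduced move set.** Moves are M→{M,I,D}, I→{I,M}, D→{D,M}. Training
  rows whose inserts abut a deletion cannot be expressed in this move
  set; such residues contribute emission counts only, with the
  flanking transition counted as if the insert were absent.

`viterbi_local()` returns the best path with its model/sequence spans
and the per-position model-column map (needed by the coverage filter);
`forward_local()` returns the total log-odds over all local paths and
is always at least the Viterbi score. Both kernels are verified against
complete enumeration of all legal paths on tiny models (≤ 4 match
columns, sequences ≤ 6 nt) — the enumeration is written independently
of the dynamic programme.

## Genome scanning and the two-end filter

`scan_genome()` scans both strands in windows of 3× the model length,
stepped by half a window, rather than running one chromosome-length
dynamic programme; overlapping same-strand hits are merged keeping the
best score. Reverse-strand hits are reported on forward coordinates.

A genuine full-length family member must resemble *both* ends of the
model; spurious hits resemble one. `two_end_filter()` keeps hits whose
aligned coverage of the model's 5' region and 3' region are each
strictly greater than `min_end_cov` (default 100 bp). The model "ends"
default to the first and last 35% of match columns — the boundary is a
package choice (configurable), since only the 100-bp coverage rule
itself is externally specified. Coverage is measured in genomic base
pairs aligned to match columns, honouring the base-pair wording of the
rule.

## Promoter grammar and polymerase specificity

Drosophila snRNA promoters follow a compact grammar: a proximal
sequence element (PSE) 8 bp upstream of a TATA box, itself 18 bp
upstream of the TSS, marks Pol III-type genes (like U6); a PSE with a
PSEB element instead of the TATA marks Pol II-type genes (U1–U5). A TC
dinucleotide at PSE alignment positions 19–20 is the strongest single
discriminator of Pol III specificity.

* **PWMs.** The shipped PSE/TATA/PSEB matrices are consensus-derived
  synthetic defaults (85% weight on the consensus base), not empirical
  alignments — the generator implants the same consensi, so defaults
  and simulations are mutually consistent. Match floor: 0.75 of the
  maximum achievable log-odds. All matrices are plain R objects and
  can be replaced wholesale.
* **Spacing tolerance.** ±2 bp around the canonical 8/18 geometry.
  Promoters in this family can show only marginal TATA similarity, so
  a rigid spacing requirement would be wrong; the tolerance is
  configurable through `promoter_constraints()`.
* **TC anchor.** The TC position defaults to PSE alignment column 19
  (1-based) and is configurable, because the column registration of a
  PSE alignment depends on how the matrix was built.
* **Verdict.** PSE + TC + TATA → `POL3_TYPE`; PSE without TC + PSEB →
  `POL2_TYPE`; a lone PSE or conflicting evidence → `AMBIGUOUS`; no
  PSE → `NONE`. Ties in a PWM scan resolve to the match nearest the
  TSS.

`refine_tss()` uses this grammar to anchor an approximate homology hit
to a precise +1: candidate positions around the hit start are scored
by PSE+TATA strength minus a spacing penalty. On simulated loci this
recovers the implanted TSS exactly.

## Terminators and the gene model

Runs of ≥ 4 thymidines on the sense strand terminate Pol III
transcription efficiently (in roughly 75–95% of genes — a figure the
reports cite as context; no termination-probability model is fitted,
because none is defined for this locus class). `find_t_tracks()`
reports maximal runs; `call_terminator()` reports the first run, as a
DOUBLE call when a second run follows within 3 non-T nucleotides (the
gap default is a package choice; the motivating locus shows the two
runs adjacent).

`build_gene_model()` walks the sense strand downstream of the TSS. By
default it terminates the gene at the first **double** track
(`require_double = TRUE`): the locus class this package targets has
isolated internal T-tracks upstream of a genuine double-track
terminator, and stopping at the first single run would make the gene
end at an internal track. With `require_double = FALSE` the first
qualifying run of any kind ends the gene. Gene length is inclusive
from the +1 to the terminator's first T.

The internal-track inventory is reported three ways: all runs ≥ 4 T,
runs of exactly 4–5 T (the classical efficient signals), and runs
within the first 100 nt — the ambiguity of "4 to 5 thymidines" versus
"at least 4" is thereby visible rather than hidden. `pol3_plausible`
is `TRUE` only when no internal run ≥ 4 T exists: a track-littered
gene body is not a credible Pol III transcription unit even when its
promoter looks Pol III-type.

## Secondary structure

`fold_rna()` is a Nussinov-style maximum-score dynamic programme with
a stacking bonus: pair scores GC = 3, AU = 2, GU = 1, +1 per stacked
pair, minimum loop 3. These are *scores in arbitrary units*, not free
energies — reproducing a thermodynamic folder is out of scope, and the
downstream checks need topology (which positions pair), not energies.
The reported `energy` is the negated score so that lower = more
stable. Tie-breaks are deterministic (prefer the pair with the smaller
5' index, then the smaller partner). Any external folder can be
substituted through the dot-bracket seam (`read_dotbracket()` /
`new_rna_structure()`, which enforce all structural invariants).

* `check_core()` counts pairs joining the terminal windows (default
  25 nt each); ≥ 4 such pairs call the closed 5'–3' core that
  scaffolds the 7SK snRNP. The 5'-terminal window is searched for the
  GAUC tetrad of the HEXIM-contacting stem, reporting the GAUG
  variant when present.
* `verify_motifs()` verifies — it does not discover — annotated
  intervals (M1/M3/M8, stems A/B): an interval is confirmed when ≥ 3
  pairs lie entirely inside it. Motif coordinates are inputs, exactly
  as conserved-motif annotations on a reference structure are.

The folder is verified against complete enumeration of all valid
structures for sequences up to 14 nt. One subtlety the tests encode:
the optimum is invariant under sequence *reversal* (the pair scores
are symmetric), but not under reverse-complementation, because a GU
wobble maps to an unpairable AC.

## In-silico PCR and dilution arithmetic

`find_amplicon()` pairs the leftmost forward-primer site with the
nearest downstream reverse site. Matching is exact by default (no
mismatch tolerance is externally specified); when mismatches are
allowed, the 3'-terminal 3 nt of either primer must still match
exactly, since 3' mismatches abolish extension.

Semi-quantitative RT-PCR quantifies by serial 5-fold dilution:
`least_saturated_dilution()` picks the smallest exponent whose band is
detectable but below the saturation threshold (default 0.9 of the
detector maximum — band saturation is judged by eye in practice, so
the threshold is explicit configuration). `relative_expression()`
reads the target/reference ratio at the reference's chosen exponent
and refuses to interpolate missing measurements. Samples read at
exponents $e_1$ and $e_2$ with equal band intensities differ by
$5^{e_1-e_2}$ in input.

## The synthetic generator

`make_cassette()` + `make_genome()` build the study system with known
truth:

* promoter: PSE (21 bp, TC at 19–20), 8-bp spacer, TATA (8 bp, 3'
  G), 18-bp gap, TSS on an adenine;
* gene: 404 bp inclusive of the terminator's first T; five internal
  T4–T5 tracks, four of them in the first 100 nt; a 4+6 double-T
  terminator separated by one non-T base;
* structure: complementary 12-nt termini that fold into a closed core
  whose 5' window carries GAUG (and never GAUC); five designed 8-bp
  GC-only hairpins at the annotated motif intervals;
* primers: a forward primer inside the gene and a reverse primer
  placed for a 210-nt product, plus a forward primer upstream of the
  TSS that yields no product on the transcript.

Screens keep the construction honest: filler sequence can never form
an oligo-T run; bases flanking implanted tracks (and implant
boundaries in the genome) are pinned non-T so implanted runs stay
maximal; the promoter region is rejected if it contains a spurious
element consensus; and the body filler is resampled until the folded
gene actually realises the designed hairpins and core — without that
last screen, roughly one filler in ten would let a GC-rich stretch
outcompete a designed stem in the global fold. GC-only stems were
chosen so that no stem arm shares a complementary run longer than 5
with any other arm, and so that stems cannot pair with the U-tracks.

`make_family()` mutates a seed (by default the cassette gene) with
per-site substitutions and single-nucleotide indels, reconstructing
the gapped alignment from the known edit history, so insert columns
are exact truth and no aligner enters the loop. Under
substitution-only divergence the expected pairwise identity is
$(1-s)^2 + s^2/3$, which the tests check against simulation.

**What the simulations do not emulate:** real genome composition
(repeats, isochores, Markov structure — the background is i.i.d. at a
fixed GC), introns (the motivating locus sits inside one), pseudogene
fields, or sequencing error. Passing the recovery suite therefore
demonstrates algorithmic correctness under the stated geometry, not
sensitivity/specificity on a real genome; the scan of a real assembly
additionally depends on the quality of the training alignment.

## Problem sizes and defaults used by the shipped analyses

The `analysis/` drivers and the acceptance script use: one 2.5-kb
contig at GC 0.43 with one implanted cassette; families of 8 members
at 8% substitution and 1% indel; scan windows of 3× the model length
at a 30-bit threshold with the >100-bp two-end rule; 20 independent
seeds for the recovery experiment; 400 seeded trials for the
promoter-spacing property. These sizes give stable, exactly
reproducible statistics (recovery is 20/20 with every parameter
recovered exactly) while keeping a full run in tens of seconds.

## Known limitations

* The HMM has no E-value calibration; thresholds are in bits and were
  chosen for the synthetic regime. On a real genome, calibrate against
  a shuffled background.
* The folder's scores are not comparable across sequences of different
  lengths and must not be read as kcal/mol.
* Promoter PWMs are synthetic defaults; real applications should
  supply matrices estimated from curated promoter alignments.
* The interface is the package's functions plus the numbered scripts
  under `analysis/`; there is no shell-level subcommand wrapper.
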