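# Ground-truthed synthetic data: divergent ncRNA families for HMM
# training, and genomes with implanted snRNA gene cassettes (promoter +
# gene body + Pol III terminator) for end-to-end recovery experiments.
#
# The default cassette reproduces the geometry of the Drosophila
# snRNA:7SK:94F-like locus: a 21-bp PSE with the TC dinucleotide at
# positions 19-20, an 8-bp spacer, a TATA box 18 bp upstream of the TSS
# (an adenine), a 404-bp gene whose 3' end is a double track of 4 and 6
# thymidines, five internal T4-T5 tracks mainly in the first hundred
# nucleotides, five designed hairpin motifs (M1/M3/M8 and stems A/B),
# and complementary termini that fold into a closed 5'-3' core whose 5'
# stem carries GAUG (the GAUC variant seen in canonical 7SK is a
# one-base edit away).

# 5'-terminal core arm: starts with the TSS adenine and carries GAUG
core5_arm <- function() "AGATGCCGGCAC"

# GC-only stems chosen so that no arm shares a complementary run longer
# than 5 with any other arm (or with the core arms): the designed 8-pair
# helices cannot be outscored by a cross-hairpin pairing, and GC-only
# arms cannot pair with the oligo-U tracks of the gene body
default_motif_stems <- function() {
  c(M1 = "GGCGGGCG", M3 = "GCCCGGCG", M8 = "CCGGCCCC",
    STEM_A = "CGGGGGGC", STEM_B = "GCGCGGCG")
}

#' Specification of a synthetic snRNA gene cassette
#'
#' Defaults reproduce the canonical geometry described above; every
#' piece is configurable. Offsets of internal T-tracks and motifs are
#' 1-based gene positions (TSS = 1). The terminator's first T sits at
#' gene position `body_len`, so the gene is `body_len` bp from TSS to
#' terminator start inclusive.
#'
#' @param pse_seq PSE sequence (default the shipped 21-bp consensus).
#' @param spacer_len PSE-TATA spacer length in bp (default 8).
#' @param tata_seq TATA box sequence, or `NULL` for a promoter without
#'   TATA (default the shipped 8-bp consensus).
#' @param pseb_seq optional PSEB sequence replacing the TATA box (Pol
#'   II-type promoter); default `NULL`.
#' @param tata_tss_gap gap between TATA (or PSEB) end and the TSS in bp
#'   (default 18).
#' @param body_len gene length in bp, TSS to terminator start inclusive
#'   (default 404).
#' @param internal_t_tracks data frame with `offset` and `length` of the
#'   internal oligo-T tracks (gene positions).
#' @param terminator_tracks lengths of the two terminator T-runs
#'   (default c(4, 6)).
#' @param terminator_gap non-T nucleotides between the two runs
#'   (default 1).
#' @param motifs data frame with `name` and `start` of designed hairpin
#'   motifs (each occupies 20 nt: an 8-bp stem, 4-nt loop, 8-bp
#'   reverse-complement stem).
#' @param strand implantation strand (default "+").
#' @param gc_background GC content of filler sequence (default 0.43).
#' @return a list of class `cassette_spec`.
#' @export
cassette_spec <- function(pse_seq = default_pse_consensus(),
                          spacer_len = 8,
                          tata_seq = default_tata_consensus(),
                          pseb_seq = NULL,
                          tata_tss_gap = 18,
                          body_len = 404,
                          internal_t_tracks = data.frame(
                            offset = c(20, 45, 70, 95, 150),
                            length = c(4, 5, 4, 5, 4)),
                          terminator_tracks = c(4, 6),
                          terminator_gap = 1,
                          motifs = data.frame(
                            name = c("M1", "M3", "M8", "STEM_A", "STEM_B"),
                            start = c(170, 200, 230, 260, 290)),
                          strand = "+",
                          gc_background = 0.43) {
  stopifnot(spacer_len >= 0, tata_tss_gap >= 0, body_len >= 1,
            terminator_gap >= 0, strand %in% c("+", "-"))
  if (!is.null(tata_seq) && !is.null(pseb_seq))
    stop("supply either tata_seq or pseb_seq, not both", call. = FALSE)
  if (nrow(internal_t_tracks)) {
    ends <- internal_t_tracks$offset + internal_t_tracks$length - 1
    if (any(internal_t_tracks$offset < 2) || any(ends >= body_len))
      stop("internal T-tracks must lie strictly inside the gene body",
           call. = FALSE)
  }
  structure(list(pse_seq = norm_dna(pse_seq), spacer_len = spacer_len,
                 tata_seq = if (is.null(tata_seq)) NULL else
                   norm_dna(tata_seq),
                 pseb_seq = if (is.null(pseb_seq)) NULL else
                   norm_dna(pseb_seq),
                 tata_tss_gap = tata_tss_gap, body_len = body_len,
                 internal_t_tracks = internal_t_tracks,
                 terminator_tracks = terminator_tracks,
                 terminator_gap = terminator_gap, motifs = motifs,
                 strand = strand, gc_background = gc_background),
            class = "cassette_spec")
}

# filler that cannot create oligo-T runs; resampled until it avoids the
# given forbidden exact substrings in its local context
screened_filler <- function(n, gc, context_fun = NULL, forbidden = NULL,
                            tries = 50) {
  for (k in seq_len(tries)) {
    f <- random_dna(n, gc, max_t_run = 4)
    if (is.null(context_fun)) return(f)
    ctx <- context_fun(f)
    if (!any(vapply(forbidden, grepl, logical(1), x = ctx,
                    fixed = TRUE))) return(f)
  }
  stop("could not generate screened filler", call. = FALSE)
}

#' Build a synthetic gene cassette from a specification
#'
#' Assembles promoter + gene + terminator with every element's position
#' recorded as ground truth. Random filler is screened so that the gene
#' body carries no oligo-T run other than the specified tracks, flanks
#' of implanted tracks keep them maximal, the promoter region contains
#' no spurious element consensus, and the 5'-terminal window contains
#' GAUG but not GAUC.
#'
#' @param spec a [cassette_spec()].
#' @return a list of class `cassette` with the cassette `sequence`, the
#'   `tss_offset` within it, `gene_seq` (TSS to terminator start),
#'   `rna_seq`, element coordinates relative to cassette and gene,
#'   designed `motifs`, and a `primers` set (PU15/PU12 bracketing a
#'   210-nt amplicon by default, plus an upstream PU10).
#' @export
make_cassette <- function(spec = cassette_spec()) {
  stopifnot(inherits(spec, "cassette_spec"))
  gc <- spec$gc_background
  pse <- spec$pse_seq
  box <- if (!is.null(spec$tata_seq)) spec$tata_seq else spec$pseb_seq
  if (is.null(box)) stop("cassette needs a TATA or PSEB element",
                         call. = FALSE)
  consensi <- c(default_pse_consensus(), default_tata_consensus(),
                default_pseb_consensus(), pse, box)
  spacer <- screened_filler(spec$spacer_len, gc,
                            context_fun = identity, forbidden = consensi)
  gap <- screened_filler(spec$tata_tss_gap, gc,
                         context_fun = identity, forbidden = consensi)
  upstream <- paste0(pse, spacer, box, gap)
  tss_offset <- nchar(upstream) + 1L

  # ---- gene body -------------------------------------------------------
  n <- spec$body_len
  v <- rep(NA_character_, n - 1)  # positions 1 .. body_len-1; T1 of the
                                  # terminator occupies position body_len
  place <- function(s, at) {
    w <- strsplit(s, "")[[1]]
    idx <- at:(at + length(w) - 1)
    if (at < 1 || max(idx) > length(v))
      stop("cassette element does not fit in the gene body", call. = FALSE)
    if (!all(is.na(v[idx])))
      stop("cassette elements overlap; adjust offsets", call. = FALSE)
    v[idx] <<- w
  }
  core5 <- core5_arm()
  core3 <- revcomp(core5)  # ends with T: doubles as terminator T1 context
  place(core5, 1)
  # core3 occupies the last nchar(core3) gene positions, its final base
  # at position body_len (the terminator's first T)
  c3 <- strsplit(core3, "")[[1]]
  if (c3[length(c3)] != "T")
    stop("3' core arm must end in T to seed the terminator", call. = FALSE)
  v[(n - length(c3) + 1):(n - 1)] <- c3[-length(c3)]

  stems <- default_motif_stems()
  motifs <- spec$motifs
  if (nrow(motifs)) {
    motifs$end <- motifs$start + 19L
    for (k in seq_len(nrow(motifs))) {
      st <- stems[[((k - 1) %% length(stems)) + 1]]
      hp <- paste0(st, "GAAA", revcomp(st))
      place(hp, motifs$start[k])
    }
  }
  tt <- spec$internal_t_tracks
  if (nrow(tt)) {
    for (k in seq_len(nrow(tt)))
      place(strrep("T", tt$length[k]), tt$offset[k])
  }
  # fill remaining positions with screened background, non-T at track
  # flanks so implanted runs stay maximal; when the cassette carries
  # designed hairpin motifs, the filler is resampled until the folded
  # gene honours the design contract (every motif verified, core
  # closed) — rejection sampling against fillers that would pair with
  # a stem arm and dissolve a designed helix
  flank_pos <- integer(0)
  if (nrow(tt)) {
    flank_pos <- c(tt$offset - 1L, tt$offset + tt$length)
    flank_pos <- flank_pos[flank_pos >= 1 & flank_pos <= length(v)]
  }
  open <- which(is.na(v))
  term <- paste0(strrep("T", spec$terminator_tracks[1]),
                 screened_filler_nonT(spec$terminator_gap, gc),
                 strrep("T", spec$terminator_tracks[2]))
  w25 <- min(25, length(v))
  for (try in seq_len(60)) {
    v[open] <- NA_character_
    for (i in open) {
      repeat {
        b <- sample(NT, 1, prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                    (1 - gc) / 2))
        if (b == "T" && i %in% flank_pos) next
        # no new T-run of 4: look back three filled positions
        if (b == "T" && i > 3 && !anyNA(v[(i - 3):(i - 1)]) &&
            all(v[(i - 3):(i - 1)] == "T")) next
        v[i] <- b
        break
      }
    }
    # 5'-window screen: GAUG (from the core arm) but never GAUC up front
    redo <- intersect(open, seq_len(w25))
    while (grepl("GATC", paste(v[1:w25], collapse = ""), fixed = TRUE) &&
           length(redo)) {
      for (i in redo) v[i] <- sample(c("A", "C", "G"), 1)
    }
    gene <- paste0(paste(v, collapse = ""), term)
    if (!nrow(motifs) || nchar(gene) < 8) break
    st <- fold_rna(substr(gene, 1, n))
    ok <- all(verify_motifs(st, motifs)$verified) && check_core(st)$closed
    if (ok) break
    if (try == 60)
      stop("could not realise the designed fold; adjust the cassette spec",
           call. = FALSE)
  }
  gene_seq <- substr(gene, 1, n)  # TSS .. terminator start
  cassette <- paste0(upstream, gene)

  # primers: forward inside the gene, reverse chosen for a 210-nt product
  amp_len <- 210L
  fwd_at <- 100L
  rev_end <- fwd_at + amp_len - 1L
  primers <- c(
    PU15 = substr(gene_seq, fwd_at, fwd_at + 19L),
    PU12 = revcomp(substr(gene_seq, rev_end - 19L, rev_end)),
    PU10 = substr(upstream, 10L, 29L))

  box_type <- if (!is.null(spec$tata_seq)) "TATA" else "PSEB"
  elements <- data.frame(
    type = c("PSE", box_type, "TSS", "gene", "terminator"),
    start = c(1L, nchar(pse) + spec$spacer_len + 1L, tss_offset,
              tss_offset, tss_offset + n - 1L),
    end = c(nchar(pse),
            nchar(pse) + spec$spacer_len + nchar(box),
            tss_offset, tss_offset + n - 1L,
            nchar(cassette)))

  structure(list(
    spec = spec, sequence = cassette, tss_offset = tss_offset,
    gene_seq = gene_seq, rna_seq = chartr("T", "U", gene_seq),
    elements = elements,
    internal_t_tracks = tt,
    terminator = list(offset = n, track_lengths = spec$terminator_tracks,
                      gap = spec$terminator_gap),
    motifs = if (nrow(motifs)) motifs[, c("name", "start", "end")] else
      motifs,
    primers = primers, amplicon_length = amp_len,
    strand = spec$strand
  ), class = "cassette")
}

# gap filler between terminator tracks: never T
screened_filler_nonT <- function(n, gc) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G"), n, replace = TRUE,
               prob = c((1 - gc), gc, gc) / (1 + gc)), collapse = "")
}

#' Generate a divergent sequence family and its alignment
#'
#' Members derive from one seed sequence by per-site substitutions and
#' single-nucleotide indels; the gapped alignment is reconstructed from
#' the known edit history (no aligner is invoked), so insert columns are
#' exact ground truth.
#'
#' @param n_members number of family members (>= 2).
#' @param seed_length length of the random seed sequence (ignored when
#'   `template` is given).
#' @param substitution_rate per-site substitution probability in [0, 1).
#' @param indel_rate per-site indel probability in [0, 1) (half
#'   deletions, half single-nt insertions).
#' @param seed RNG seed for reproducibility (optional).
#' @param template explicit seed sequence (e.g. a cassette gene) to
#'   mutate instead of a random one.
#' @param gc GC content of a random seed sequence.
#' @return an `msa_aln` with an extra `seed_seq` element holding the
#'   ungapped seed.
#' @export
make_family <- function(n_members, seed_length = 404,
                        substitution_rate = 0.05, indel_rate = 0.01,
                        seed = NULL, template = NULL, gc = 0.43) {
  stopifnot(n_members >= 2, substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  seedv <- if (!is.null(template)) strsplit(norm_dna(template), "")[[1]]
           else strsplit(random_dna(seed_length, gc), "")[[1]]
  L <- length(seedv)
  if (L == 0) stop("seed sequence is empty", call. = FALSE)

  rows_res <- matrix("", n_members, L)      # residue ('-' = deleted)
  rows_ins <- matrix("", n_members, L)      # single-nt insertion after i
  for (m in seq_len(n_members)) {
    del <- stats::runif(L) < indel_rate / 2
    sub <- stats::runif(L) < substitution_rate
    ins <- stats::runif(L) < indel_rate / 2
    res <- seedv
    if (any(sub)) {
      res[sub] <- vapply(seedv[sub], function(b)
        sample(setdiff(NT, b), 1), character(1))
    }
    res[del] <- "-"
    rows_res[m, ] <- res
    rows_ins[m, ins] <- vapply(which(ins), function(i) sample(NT, 1),
                               character(1))
  }
  ins_cols <- which(colSums(rows_ins != "") > 0)
  rows <- vapply(seq_len(n_members), function(m) {
    parts <- character(0)
    for (i in seq_len(L)) {
      parts <- c(parts, rows_res[m, i])
      if (i %in% ins_cols)
        parts <- c(parts, if (nzchar(rows_ins[m, i])) rows_ins[m, i]
                   else "-")
    }
    paste(parts, collapse = "")
  }, character(1))
  names(rows) <- sprintf("member%02d", seq_len(n_members))
  aln <- new_alignment(rows)
  aln$seed_seq <- paste(seedv, collapse = "")
  aln
}

#' Generate a synthetic genome with implanted gene cassettes
#'
#' Background is i.i.d. with the requested GC content; cassettes are
#' implanted at recorded non-overlapping positions on their requested
#' strands, and the 50 bp flanking each implant are screened free of
#' oligo-T (and oligo-A) runs of 4 or more so no spurious terminator or
#' track touches an implant boundary.
#'
#' @param cassettes list of `cassette` objects from [make_cassette()].
#' @param n_contigs number of contigs (default 1).
#' @param contig_len length of each contig in bp.
#' @param gc background GC fraction (default 0.43).
#' @param seed RNG seed (optional).
#' @param margin minimum distance of an implant from contig ends and
#'   between implants (default 150).
#' @return a list of class `synthetic_genome`: `sequences` (named
#'   character vector), `truth` (data frame of implanted features in
#'   genomic coordinates), `cassettes` (with placement), `gc`.
#' @export
make_genome <- function(cassettes, n_contigs = 1, contig_len = 3000,
                        gc = 0.43, seed = NULL, margin = 150) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(cassettes) >= 1)
  seqs <- vapply(seq_len(n_contigs), function(i)
    random_dna(contig_len, gc), character(1))
  names(seqs) <- sprintf("ctg%d", seq_len(n_contigs))

  assign_ctg <- rep(seq_len(n_contigs), length.out = length(cassettes))
  placements <- list()
  truth <- list()
  for (ci in seq_len(n_contigs)) {
    idx <- which(assign_ctg == ci)
    if (!length(idx)) next
    lens <- vapply(cassettes[idx], function(x) nchar(x$sequence),
                   integer(1))
    need <- sum(lens) + (length(idx) + 1L) * margin
    if (need > contig_len)
      stop("cassettes cannot be placed: contig too short", call. = FALSE)
    # choose ordered non-overlapping starts
    free <- contig_len - sum(lens) - (length(idx) + 1L) * margin
    cuts <- sort(sample.int(free + 1L, length(idx), replace = TRUE)) - 1L
    starts <- margin + 1L + cuts +
      cumsum(c(0L, lens[-length(lens)])) +
      (seq_along(idx) - 1L) * margin
    s <- seqs[[ci]]
    for (k in seq_along(idx)) {
      cs <- cassettes[[idx[k]]]
      ins <- if (cs$strand == "+") cs$sequence else revcomp(cs$sequence)
      a <- starts[k]; b <- a + nchar(cs$sequence) - 1L
      substr(s, a, b) <- ins
      placements[[idx[k]]] <- list(contig = names(seqs)[ci], start = a,
                                   end = b, strand = cs$strand)
      truth[[idx[k]]] <- cassette_truth(cs, names(seqs)[ci], a)
    }
    # screen 50-bp flanks of every implant for runs of T or A >= 4, and
    # pin the immediately adjacent bases to C/G so boundary runs of the
    # cassette (e.g. the terminal T-track) stay maximal
    v <- strsplit(s, "")[[1]]
    for (k in seq_along(idx)) {
      a <- placements[[idx[k]]]$start; b <- placements[[idx[k]]]$end
      if (a > 1) v[a - 1] <- sample(c("C", "G"), 1)
      if (b < contig_len) v[b + 1] <- sample(c("C", "G"), 1)
      for (rng in list(seq(max(1, a - 50), a - 1),
                       seq(b + 1, min(contig_len, b + 50)))) {
        if (!length(rng)) next
        run <- 1L
        for (i in rng[-1]) {
          run <- if (v[i] %in% c("A", "T") && v[i] == v[i - 1]) run + 1L
                 else 1L
          if (run >= 4L) {
            v[i] <- sample(c("C", "G"), 1)
            run <- 1L
          }
        }
      }
    }
    seqs[[ci]] <- paste(v, collapse = "")
  }
  truth_df <- do.call(rbind, truth)
  rownames(truth_df) <- NULL
  for (k in seq_along(cassettes))
    cassettes[[k]]$placement <- placements[[k]]
  structure(list(sequences = seqs, truth = truth_df,
                 cassettes = cassettes, gc = gc),
            class = "synthetic_genome")
}

# genomic-coordinate truth records for one implanted cassette
cassette_truth <- function(cs, contig, at) {
  Lc <- nchar(cs$sequence)
  map <- function(a, b) {
    if (cs$strand == "+") as.integer(c(at + a - 1L, at + b - 1L))
    else as.integer(c(at + Lc - b, at + Lc - a))
  }
  rel <- cs$elements
  # gene-relative features -> cassette-relative
  g0 <- cs$tss_offset - 1L
  rows <- list(data.frame(type = "cassette", name = "cassette",
                          a = 1L, b = Lc))
  rows <- c(rows, lapply(seq_len(nrow(rel)), function(k)
    data.frame(type = rel$type[k], name = rel$type[k],
               a = rel$start[k], b = rel$end[k])))
  if (nrow(cs$internal_t_tracks)) {
    tt <- cs$internal_t_tracks
    rows <- c(rows, lapply(seq_len(nrow(tt)), function(k)
      data.frame(type = "t_track", name = sprintf("t_track%d", k),
                 a = g0 + tt$offset[k],
                 b = g0 + tt$offset[k] + tt$length[k] - 1L)))
  }
  if (!is.null(cs$motifs) && nrow(cs$motifs)) {
    rows <- c(rows, lapply(seq_len(nrow(cs$motifs)), function(k)
      data.frame(type = "motif", name = cs$motifs$name[k],
                 a = g0 + cs$motifs$start[k],
                 b = g0 + cs$motifs$end[k])))
  }
  df <- do.call(rbind, rows)
  gcoord <- t(vapply(seq_len(nrow(df)), function(k)
    map(df$a[k], df$b[k]), integer(2)))
  data.frame(contig = contig, start = gcoord[, 1], end = gcoord[, 2],
             strand = cs$strand, type = df$type, name = df$name,
             stringsAsFactors = FALSE)
}

#' Write a synthetic genome to FASTA and its truth to GFF3
#'
#' @param sg a `synthetic_genome`.
#' @param fasta_path output FASTA path.
#' @param gff3_path output GFF3 path (optional).
#' @return `fasta_path`, invisibly.
#' @export
write_genome <- function(sg, fasta_path, gff3_path = NULL) {
  x <- Biostrings::DNAStringSet(sg$sequences)
  Biostrings::writeXStringSet(x, fasta_path)
  if (!is.null(gff3_path)) {
    gr <- GenomicRanges::GRanges(
      seqnames = sg$truth$contig,
      ranges = IRanges::IRanges(start = sg$truth$start,
                                end = sg$truth$end),
      strand = sg$truth$strand, type = sg$truth$type,
      Name = sg$truth$name)
    rtracklayer::export(gr, gff3_path, format = "GFF3")
  }
  invisible(fasta_path)
}
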