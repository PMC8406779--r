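# Drosophila snRNA promoter grammar: PSE / TATA / PSEB detection by PWM
# scan, spacing checks against the canonical PSE -8bp- TATA -18bp- TSS
# geometry, and the RNA polymerase specificity verdict (the TC
# dinucleotide inside the PSE marks Pol III-type snRNA promoters;
# PSE + PSEB marks Pol II-type).

#' Build a position weight matrix from a consensus sequence
#'
#' Each column puts `weight` on the consensus base and splits the rest
#' evenly; a light-weight stand-in for a matrix estimated from a promoter
#' alignment, used for the shipped defaults.
#'
#' @param name element name.
#' @param consensus DNA consensus string.
#' @param weight probability of the consensus base per column.
#' @param min_score minimum fraction (0-1) of the maximum achievable
#'   log-odds score for a reported match.
#' @return an object of class `pwm`.
#' @export
pwm_from_consensus <- function(name, consensus, weight = 0.85,
                               min_score = 0.75) {
  consensus <- norm_dna(consensus)
  assert_alphabet(consensus, NT, "consensus")
  v <- strsplit(consensus, "")[[1]]
  if (length(v) < 4) stop("PWM length must be >= 4", call. = FALSE)
  mat <- matrix((1 - weight) / 3, length(v), 4, dimnames = list(NULL, NT))
  mat[cbind(seq_along(v), match(v, NT))] <- weight
  new_pwm(name, mat, min_score)
}

#' Construct a PWM object
#'
#' @param name element name.
#' @param matrix per-position probability matrix (rows = positions,
#'   columns A,C,G,T); rows must sum to 1.
#' @param min_score minimum fraction of maximum log-odds for a match.
#' @param background background base probabilities.
#' @return an object of class `pwm`.
#' @export
new_pwm <- function(name, matrix, min_score = 0.75,
                    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(ncol(matrix) == 4, nrow(matrix) >= 4,
            all(abs(rowSums(matrix) - 1) < 1e-9),
            min_score >= 0, min_score <= 1)
  colnames(matrix) <- NT
  structure(list(name = name, matrix = matrix, min_score = min_score,
                 background = background[NT]),
            class = "pwm")
}

#' Default promoter element PWMs
#'
#' Consensus-derived synthetic defaults for the PSE (21 bp, carrying the
#' TC dinucleotide at alignment positions 19-20), the TATA box (8 bp,
#' with the insect-typical G at its 3' end) and the PSEB element of RNA
#' Pol II-type snRNA promoters. These ship as editable defaults rather
#' than empirical matrices and pair with the synthetic cassette
#' generator, which implants the same consensi.
#'
#' @return named list of `pwm` objects: `pse`, `tata`, `pseb`.
#' @export
default_promoter_pwms <- function() {
  list(pse = pwm_from_consensus("PSE", default_pse_consensus()),
       tata = pwm_from_consensus("TATA", default_tata_consensus()),
       pseb = pwm_from_consensus("PSEB", default_pseb_consensus()))
}

#' @rdname default_promoter_pwms
#' @export
default_pse_consensus <- function() "GTCACTTTCAGGAGTTGCTCG"  # TC at 19-20

#' @rdname default_promoter_pwms
#' @export
default_tata_consensus <- function() "TATAAATG"  # 3'-terminal G

#' @rdname default_promoter_pwms
#' @export
default_pseb_consensus <- function() "CAGACGGC"

# log-odds score of every window; returns matrix of scores and max score
pwm_scan_scores <- function(upstream, pwm) {
  v <- strsplit(upstream, "")[[1]]
  w <- nrow(pwm$matrix)
  lo <- log(pwm$matrix) - matrix(log(pwm$background), w, 4, byrow = TRUE)
  idx <- match(v, NT)
  nwin <- length(v) - w + 1
  scores <- vapply(seq_len(nwin), function(s) {
    b <- idx[s:(s + w - 1)]
    if (anyNA(b)) return(-Inf)  # N or other ambiguity: window skipped
    sum(lo[cbind(seq_len(w), b)])
  }, numeric(1))
  list(scores = scores, max_score = sum(apply(lo, 1, max)))
}

#' Find the best PWM match in an upstream window
#'
#' Reports the highest-scoring window whose score reaches
#' `pwm$min_score` of the maximum achievable log-odds; ties are broken
#' towards the TSS (rightmost window).
#'
#' @param upstream nucleotide string (the promoter-proximal window).
#' @param pwm a `pwm` object.
#' @return a list `(start, end, score, seq)` with 1-based coordinates in
#'   `upstream` and `score` as the fraction of maximum, or `NULL` when no
#'   window reaches the floor.
#' @export
find_element <- function(upstream, pwm) {
  upstream <- norm_dna(upstream)
  w <- nrow(pwm$matrix)
  if (nchar(upstream) < w)
    stop("window shorter than the PWM", call. = FALSE)
  sc <- pwm_scan_scores(upstream, pwm)
  frac <- sc$scores / sc$max_score
  ok <- which(frac >= pwm$min_score - 1e-12)
  if (length(ok) == 0) return(NULL)
  best <- max(frac[ok])
  s <- max(ok[frac[ok] >= best - 1e-12])  # rightmost among ties
  list(start = s, end = s + w - 1L, score = frac[s],
       seq = substr(upstream, s, s + w - 1L))
}

#' Spacing constraints for promoter annotation
#'
#' @param pse_tata_spacer canonical PSE-TATA spacer in bp.
#' @param tata_tss_gap canonical TATA-TSS gap in bp.
#' @param tolerance allowed deviation in bp around either spacing.
#' @param tc_position 1-based PSE alignment position where the
#'   polymerase-specificity TC dinucleotide starts.
#' @return a list of class `promoter_constraints`.
#' @export
promoter_constraints <- function(pse_tata_spacer = 8, tata_tss_gap = 18,
                                 tolerance = 2, tc_position = 19) {
  structure(list(pse_tata_spacer = pse_tata_spacer,
                 tata_tss_gap = tata_tss_gap,
                 tolerance = tolerance, tc_position = tc_position),
            class = "promoter_constraints")
}

#' Annotate snRNA promoter elements upstream of a TSS
#'
#' Scans the upstream window for PSE, TATA and PSEB matches, computes
#' the PSE-TATA spacer and TATA-TSS gap, checks them against the
#' canonical 8/18 geometry within the configured tolerance, and assigns
#' a polymerase verdict via [classify_polymerase()].
#'
#' @param upstream promoter-proximal sequence on the sense strand
#'   (coordinates are 1-based within this window).
#' @param tss_offset position of the transcription +1 relative to the
#'   window start; defaults to just past the window end.
#' @param pwms named list with `pse`, `tata`, `pseb` PWMs.
#' @param constraints a [promoter_constraints()].
#' @return an object of class `promoter_annotation` with elements
#'   `pse`, `tata`, `pseb` (each `NULL` or `(start, end, score, seq)`),
#'   `pse_tata_spacer`, `tata_tss_gap`, spacing flags and `verdict`.
#' @export
annotate_promoter <- function(upstream, tss_offset = nchar(upstream) + 1L,
                              pwms = default_promoter_pwms(),
                              constraints = promoter_constraints()) {
  upstream <- norm_dna(upstream)
  if (tss_offset < 1 || tss_offset > nchar(upstream) + 1L)
    stop("tss_offset outside the upstream window", call. = FALSE)
  find_if_room <- function(pwm)
    if (nchar(upstream) >= nrow(pwm$matrix)) find_element(upstream, pwm)
    else NULL
  pse <- find_if_room(pwms$pse)
  tata <- find_if_room(pwms$tata)
  pseb <- find_if_room(pwms$pseb)

  spacer <- if (!is.null(pse) && !is.null(tata))
    tata$start - pse$end - 1L else NA_integer_
  gap <- if (!is.null(tata)) tss_offset - tata$end - 1L else NA_integer_
  tol <- constraints$tolerance
  spacer_ok <- !is.na(spacer) &&
    abs(spacer - constraints$pse_tata_spacer) <= tol
  gap_ok <- !is.na(gap) && abs(gap - constraints$tata_tss_gap) <= tol

  ann <- structure(list(pse = pse, tata = tata, pseb = pseb,
                        pse_tata_spacer = spacer, tata_tss_gap = gap,
                        spacer_ok = spacer_ok, gap_ok = gap_ok,
                        tc_at = NULL, verdict = NA_character_),
                   class = "promoter_annotation")
  ann$verdict <- classify_polymerase(ann, if (is.null(pse)) "" else pse$seq,
                                     constraints)
  if (!is.null(pse) && nchar(pse$seq) >= constraints$tc_position + 1 &&
      substr(pse$seq, constraints$tc_position,
             constraints$tc_position + 1) == "TC")
    ann$tc_at <- c(constraints$tc_position, constraints$tc_position + 1L)
  ann
}

#' Polymerase specificity verdict from a promoter annotation
#'
#' A PSE whose alignment positions `tc_position`/`tc_position + 1`
#' (default 19-20) read TC, together with a TATA box at an acceptable
#' gap, marks a Pol III-type snRNA promoter; a PSE without the TC but
#' with a PSEB marks Pol II-type. A lone PSE or conflicting evidence is
#' AMBIGUOUS; no PSE at all is NONE.
#'
#' @param ann a `promoter_annotation` (the element slots are consulted).
#' @param pse_seq the matched PSE sequence.
#' @param constraints a [promoter_constraints()].
#' @return one of `"POL3_TYPE"`, `"POL2_TYPE"`, `"AMBIGUOUS"`, `"NONE"`.
#' @export
classify_polymerase <- function(ann, pse_seq,
                                constraints = promoter_constraints()) {
  # exact [[ ]] indexing: absent elements must read as NULL, never
  # partially match the spacing fields
  if (is.null(ann[["pse"]])) return("NONE")
  tcp <- constraints$tc_position
  if (nchar(pse_seq) < tcp + 1) {
    message("PSE match shorter than the TC position; verdict AMBIGUOUS")
    return("AMBIGUOUS")
  }
  tc <- substr(pse_seq, tcp, tcp + 1) == "TC"
  tata_ok <- !is.null(ann[["tata"]]) &&
    (is.na(ann[["tata_tss_gap"]]) || isTRUE(ann[["gap_ok"]]))
  if (tc && tata_ok) return("POL3_TYPE")
  if (!tc && !is.null(ann[["pseb"]])) return("POL2_TYPE")
  "AMBIGUOUS"
}

#' @export
print.promoter_annotation <- function(x, ...) {
  show <- function(e, nm) {
    if (is.null(e)) cat(sprintf("  %s: absent\n", nm))
    else cat(sprintf("  %s: %d-%d (%.2f) %s\n", nm, e$start, e$end,
                     e$score, e$seq))
  }
  cat("Promoter annotation:\n")
  show(x$pse, "PSE"); show(x$tata, "TATA"); show(x$pseb, "PSEB")
  cat(sprintf("  PSE-TATA spacer: %s  TATA-TSS gap: %s\n",
              x$pse_tata_spacer, x$tata_tss_gap))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}

#' Extract the sense-strand window upstream of a TSS
#'
#' @param genome genome accepted by [load_genome()].
#' @param contig contig name.
#' @param tss 1-based genomic position of the +1 nucleotide.
#' @param strand `"+"` or `"-"`.
#' @param width window width in bp (default 100), ending at `tss - 1`
#'   in sense orientation.
#' @return character scalar (sense strand).
#' @export
extract_upstream <- function(genome, contig, tss, strand = "+",
                             width = 100) {
  seqs <- load_genome(genome)
  s <- seqs[[contig]]
  if (is.null(s)) stop("unknown contig: ", contig, call. = FALSE)
  if (strand == "+") {
    substr(s, max(1, tss - width), tss - 1)
  } else {
    revcomp(substr(s, tss + 1, min(nchar(s), tss + width)))
  }
}
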