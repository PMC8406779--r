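# Secondary-structure verification for 7SK-like candidates: a
# Nussinov-style maximum-score folder with stacking bonus (scores, not
# thermodynamic free energies), the closed-core check joining the 5' and
# 3' ends, the GAUC/GAUG 5'-stem variant, and verification of annotated
# hairpin motifs (M1/M3/M8, stems A and B). An external folder can be
# plugged in through dot-bracket input.

RNA_NT <- c("A", "C", "G", "U")

default_pair_scores <- function() {
  m <- matrix(0, 4, 4, dimnames = list(RNA_NT, RNA_NT))
  m["G", "C"] <- m["C", "G"] <- 3
  m["A", "U"] <- m["U", "A"] <- 2
  m["G", "U"] <- m["U", "G"] <- 1
  m
}

#' Fold an RNA with a Nussinov-style scoring DP
#'
#' Finds a maximum-score pseudoknot-free structure under simple pair
#' scores (GC = 3, AU = 2, GU = 1) with a +1 bonus per stacked pair.
#' These are scores in arbitrary units, not thermodynamic free
#' energies; the reported `energy` is the negated score so that lower
#' means more stable, mirroring the convention of free-energy folders.
#' Ties are resolved deterministically (prefer the pair with the
#' smaller 5' index, then the smaller partner).
#'
#' @param seq RNA string (T is normalised to U), length >= 8.
#' @param min_loop minimum unpaired loop length: a pair (i, j) requires
#'   j - i > min_loop (default 3).
#' @param pair_scores 4x4 score matrix over A,C,G,U (0 = not pairable).
#' @param stack_bonus score added per stacked pair (default 1).
#' @return an object of class `rna_structure`: `sequence` (RNA),
#'   `pairs` (two-column matrix of 1-based i < j), `score`, `energy`.
#' @export
fold_rna <- function(seq, min_loop = 3, pair_scores = default_pair_scores(),
                     stack_bonus = 1) {
  if (length(seq) != 1 || nchar(seq) < 8)
    stop("sequence must be a single string of length >= 8", call. = FALSE)
  rna <- chartr("Tt", "Uu", toupper(seq))
  assert_alphabet(rna, RNA_NT, "RNA")
  code <- match(strsplit(rna, "")[[1]], RNA_NT) - 1L
  r <- nussinov_cpp(code, as.integer(min_loop), pair_scores, stack_bonus)
  pairs <- r$pairs
  if (nrow(pairs)) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  structure(list(sequence = rna, pairs = pairs, score = r$score,
                 energy = -r$score, min_loop = min_loop),
            class = "rna_structure")
}

#' Construct an `rna_structure` from a sequence and a pair list
#'
#' Validates the invariants (each position in at most one pair, no
#' crossing pairs, minimum loop, canonical/wobble pairs only). Use this
#' to wrap structures produced by an external folder, e.g. via
#' [read_dotbracket()].
#'
#' @param seq RNA or DNA string (T normalised to U).
#' @param pairs two-column matrix of 1-based pair indices, i < j.
#' @param energy optional energy/score label to carry along.
#' @param min_loop minimum loop length enforced (default 3).
#' @return an `rna_structure`.
#' @export
new_rna_structure <- function(seq, pairs, energy = NA_real_, min_loop = 3) {
  rna <- chartr("Tt", "Uu", toupper(seq))
  assert_alphabet(rna, RNA_NT, "RNA")
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  v <- strsplit(rna, "")[[1]]
  if (nrow(pairs)) {
    if (any(pairs[, 1] >= pairs[, 2])) stop("pairs must have i < j",
                                            call. = FALSE)
    if (any(pairs < 1) || any(pairs > length(v)))
      stop("pair index outside sequence", call. = FALSE)
    if (anyDuplicated(as.vector(pairs)))
      stop("a position occurs in more than one pair", call. = FALSE)
    if (any(pairs[, 2] - pairs[, 1] < min_loop + 1))
      stop("pair violates the minimum loop length", call. = FALSE)
    ps <- default_pair_scores()
    if (any(ps[cbind(v[pairs[, 1]], v[pairs[, 2]])] == 0))
      stop("non-canonical base pair", call. = FALSE)
    o <- order(pairs[, 1])
    pairs <- pairs[o, , drop = FALSE]
    for (k in seq_len(nrow(pairs) - 1)) {
      crossing <- pairs[-seq_len(k), 1] < pairs[k, 2] &
        pairs[-seq_len(k), 2] > pairs[k, 2]
      if (any(crossing)) stop("crossing pairs (pseudoknot)", call. = FALSE)
    }
  }
  structure(list(sequence = rna, pairs = pairs, score = -energy,
                 energy = energy, min_loop = min_loop),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("RNA structure: %d nt, %d pairs, score %.1f\n",
              nchar(x$sequence), nrow(x$pairs), x$score))
  cat(" ", dotbracket(x), "\n")
  invisible(x)
}

#' Dot-bracket string of a structure
#'
#' @param st an `rna_structure`.
#' @return character scalar.
#' @export
dotbracket <- function(st) {
  v <- rep(".", nchar(st$sequence))
  if (nrow(st$pairs)) {
    v[st$pairs[, 1]] <- "("
    v[st$pairs[, 2]] <- ")"
  }
  paste(v, collapse = "")
}

#' Parse a dot-bracket string into a pair matrix
#'
#' @param db dot-bracket string over `.`, `(`, `)`.
#' @return two-column matrix of 1-based pairs.
#' @export
parse_dotbracket <- function(db) {
  v <- strsplit(db, "")[[1]]
  if (!all(v %in% c(".", "(", ")")))
    stop("dot-bracket may contain only '.', '(' and ')'", call. = FALSE)
  stack <- integer(0)
  pairs <- matrix(integer(0), 0, 2)
  for (k in seq_along(v)) {
    if (v[k] == "(") stack <- c(stack, k)
    else if (v[k] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket", call. = FALSE)
      pairs <- rbind(pairs, c(stack[length(stack)], k))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket", call. = FALSE)
  colnames(pairs) <- c("i", "j")
  pairs[order(pairs[, 1]), , drop = FALSE]
}

#' Read a structure from a dot-bracket file
#'
#' Expects the Vienna-style layout: a `>` header line, the sequence
#' line, and the dot-bracket line (an optional trailing energy in
#' parentheses is parsed if present).
#'
#' @param path file path.
#' @return an `rna_structure`.
#' @export
read_dotbracket <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  if (startsWith(ln[1], ">")) ln <- ln[-1]
  seq <- trimws(ln[1])
  dbl <- trimws(ln[2])
  energy <- NA_real_
  m <- regmatches(dbl, regexec("\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", dbl))[[1]]
  if (length(m) == 2 && grepl("[0-9]", m[2])) {
    db <- trimws(sub("\\([^()]*\\)\\s*$", "", dbl))
    if (nchar(db) == nchar(seq)) {
      energy <- as.numeric(m[2])
      dbl <- db
    }
  }
  new_rna_structure(seq, parse_dotbracket(dbl), energy = energy)
}

#' Write a structure as a dot-bracket file
#'
#' @param st an `rna_structure`.
#' @param path output file.
#' @param id FASTA-style record id.
#' @return `path`, invisibly.
#' @export
write_dotbracket <- function(st, path, id = "structure") {
  writeLines(c(paste0(">", id), st$sequence,
               sprintf("%s (%.2f)", dotbracket(st), st$energy)), path)
  invisible(path)
}

#' Check the closed 5'-3' core of a folded RNA
#'
#' Counts pairs joining the 5'-terminal and 3'-terminal windows; the
#' structure is "closed" when at least `min_core_pairs` such pairs
#' exist (both ends brought together, the hallmark core of 7SK RNAs).
#' The 5'-terminal window is also searched for the GAUC tetrad of the
#' HEXIM-contacting 5' stem, reporting `GAUC`, the `GAUG` variant, or
#' `OTHER`/`ABSENT`.
#'
#' @param st an `rna_structure`.
#' @param end_window window size in nt at each end (default 25).
#' @param min_core_pairs pairs needed to call the core closed
#'   (default 4).
#' @return a list `(closed, n_end_pairs, gauc_variant)` of class
#'   `core_check`.
#' @export
check_core <- function(st, end_window = 25, min_core_pairs = 4) {
  n <- nchar(st$sequence)
  p <- st$pairs
  n_end <- if (nrow(p))
    sum(p[, 1] <= end_window & p[, 2] >= n - end_window + 1) else 0L
  closed <- n_end >= min_core_pairs
  stem5 <- substr(st$sequence, 1, min(n, end_window))
  gauc <- if (grepl("GAUC", stem5, fixed = TRUE)) "GAUC"
          else if (grepl("GAUG", stem5, fixed = TRUE)) "GAUG"
          else if (closed) "OTHER" else "ABSENT"
  structure(list(closed = closed, n_end_pairs = n_end,
                 gauc_variant = gauc), class = "core_check")
}

#' Verify annotated structural motifs against a folded structure
#'
#' A motif interval is verified when at least `min_stem_pairs` pairs lie
#' entirely within it (a local stem/hairpin exists there). Intervals are
#' inputs, mirroring how conserved motifs (M1/M3/M8, stems A/B) are
#' annotated on a reference structure; the tool verifies rather than
#' discovers them.
#'
#' @param st an `rna_structure`.
#' @param annotations data frame with columns `name`, `start`, `end`
#'   (1-based inclusive on the RNA).
#' @param min_stem_pairs pairs required inside the interval (default 3).
#' @return the annotations data frame with added `n_pairs_within`,
#'   `verified` and `evidence` columns.
#' @export
verify_motifs <- function(st, annotations, min_stem_pairs = 3) {
  stopifnot(all(c("name", "start", "end") %in% names(annotations)))
  if (anyDuplicated(annotations$name))
    stop("duplicate motif names", call. = FALSE)
  n <- nchar(st$sequence)
  if (any(annotations$start < 1) || any(annotations$end > n) ||
      any(annotations$start > annotations$end))
    stop("motif interval outside the sequence", call. = FALSE)
  p <- st$pairs
  annotations$n_pairs_within <- vapply(seq_len(nrow(annotations)),
    function(k) {
      if (!nrow(p)) return(0L)
      sum(p[, 1] >= annotations$start[k] & p[, 2] <= annotations$end[k])
    }, integer(1))
  annotations$verified <- annotations$n_pairs_within >= min_stem_pairs
  annotations$evidence <- sprintf(
    "%d pairs within %d-%d (>= %d required)",
    annotations$n_pairs_within, annotations$start, annotations$end,
    min_stem_pairs)
  annotations
}
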