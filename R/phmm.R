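# Nucleotide profile HMM: construction from a multiple alignment and
# local log-odds scoring (Viterbi and forward) of sequences.

#' Build a nucleotide profile HMM from a multiple alignment
#'
#' Columns whose gap fraction is at most `gap_fraction_threshold` become
#' match states; remaining columns feed the (position-independent) insert
#' state. Emissions and transitions receive simple Laplace pseudocounts.
#' The background distribution is the pseudocounted overall residue
#' frequency of the alignment.
#'
#' Transition counts are taken from each row's path through the model
#' (match = residue, delete = gap at a match column, insert = residue in
#' a non-match column). Inserts flanked by a deletion cannot be expressed
#' in the reduced M/I/D move set (no I-D or D-I moves), so such residues
#' contribute emission counts only and the flanking transition is counted
#' as if the insert were absent.
#'
#' @param aln an `msa_aln` from [read_alignment()] or [new_alignment()].
#' @param gap_fraction_threshold columns with gap fraction above this are
#'   insert columns (default 0.5).
#' @param pseudocount Laplace pseudocount added per symbol/transition
#'   (default 1).
#' @return an object of class `profile_hmm`.
#' @export
build_profile <- function(aln, gap_fraction_threshold = 0.5,
                          pseudocount = 1.0) {
  stopifnot(inherits(aln, "msa_aln"), pseudocount > 0)
  M <- aln_matrix(aln)
  nseq <- nrow(M)
  gapfrac <- colMeans(M == "-")
  match_cols <- which(gapfrac <= gap_fraction_threshold)
  n <- length(match_cols)
  if (n == 0) stop("no match columns at this gap-fraction threshold",
                   call. = FALSE)
  pc <- pseudocount

  count4 <- function(v) {
    c(A = sum(v == "A"), C = sum(v == "C"), G = sum(v == "G"),
      T = sum(v == "T"))
  }
  me <- t(vapply(match_cols, function(j) {
    cnt <- count4(M[, j])
    (cnt + pc) / (sum(cnt) + 4 * pc)
  }, numeric(4)))
  colnames(me) <- NT

  ins_cols <- setdiff(seq_len(ncol(M)), match_cols)
  icnt <- if (length(ins_cols)) count4(M[, ins_cols, drop = FALSE]) else
    stats::setNames(numeric(4), NT)
  ie <- (icnt + pc) / (sum(icnt) + 4 * pc)

  bcnt <- count4(M)
  bg <- (bcnt + pc) / (sum(bcnt) + 4 * pc)

  # transition counts between consecutive match columns
  cM <- matrix(0, max(n - 1, 0), 3, dimnames = list(NULL, c("M", "I", "D")))
  cI <- matrix(0, max(n - 1, 0), 2, dimnames = list(NULL, c("M", "I")))
  cD <- matrix(0, max(n - 1, 0), 2, dimnames = list(NULL, c("M", "D")))
  if (n > 1) {
    is_res <- M != "-"
    for (s in seq_len(nseq)) {
      st <- ifelse(is_res[s, match_cols], "M", "D")
      for (k in seq_len(n - 1)) {
        between <- ins_cols[ins_cols > match_cols[k] &
                              ins_cols < match_cols[k + 1]]
        ni <- if (length(between)) sum(is_res[s, between]) else 0L
        a <- st[k]; b <- st[k + 1]
        if (ni > 0 && a == "M" && b == "M") {
          cM[k, "I"] <- cM[k, "I"] + 1
          if (ni > 1) cI[k, "I"] <- cI[k, "I"] + (ni - 1)
          cI[k, "M"] <- cI[k, "M"] + 1
        } else if (a == "M") {
          cM[k, b] <- cM[k, b] + 1
        } else {
          cD[k, b] <- cD[k, b] + 1
        }
      }
    }
  }
  norm_rows <- function(cnt) {
    p <- cnt + pc
    p / rowSums(p)
  }
  trans <- list(from_m = norm_rows(cM), from_i = norm_rows(cI),
                from_d = norm_rows(cD))

  structure(list(
    n_match = n,
    match_emissions = me,
    insert_emissions = ie,
    transitions = trans,
    background = bg,
    column_map = match_cols,
    pseudocount = pc,
    gap_fraction_threshold = gap_fraction_threshold
  ), class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("Profile HMM: %d match columns (alignment length %d)\n",
              x$n_match, max(x$column_map)))
  cat(sprintf("  background: %s\n",
              paste(sprintf("%s=%.3f", NT, x$background), collapse = " ")))
  invisible(x)
}

#' Consensus sequence of a profile HMM
#'
#' The highest-emission base at every match column.
#'
#' @param model a `profile_hmm`.
#' @return character scalar.
#' @export
consensus_seq <- function(model) {
  paste(NT[apply(model$match_emissions, 1, which.max)], collapse = "")
}

# log-odds parameterisation handed to the C++ kernels (nats)
phmm_log_par <- function(model) {
  lbg <- log(model$background)
  lom <- log(model$match_emissions) -
    matrix(lbg, model$n_match, 4, byrow = TRUE)
  loi <- log(model$insert_emissions) - lbg
  list(lom = lom, loi = as.numeric(loi),
       ltm = log(model$transitions$from_m),
       lti = log(model$transitions$from_i),
       ltd = log(model$transitions$from_d))
}

check_scan_seq <- function(seq) {
  if (length(seq) != 1 || !nzchar(seq))
    stop("sequence must be a nonempty string", call. = FALSE)
  s <- norm_dna(seq)
  assert_alphabet(s, c("A", "C", "G", "T", "N"))
  s
}

#' Local Viterbi alignment of a sequence to a profile HMM
#'
#' Local-local alignment: entry is free into any match column, exit free
#' from any match column, flanking sequence unscored. The empty
#' alignment scores 0, so the reported log-odds is never negative.
#' N residues emit at background (log-odds contribution 0).
#'
#' @param model a `profile_hmm`.
#' @param seq nucleotide string (A/C/G/T/N; U and lowercase accepted).
#' @return an object of class `phmm_score`: `log_odds` (bits), `nats`,
#'   `best_path` (string over M/I/D), `model_span`, `seq_span`, and
#'   `col_of_pos` (model match column aligned to each sequence position
#'   of the span; 0 for insert-aligned positions).
#' @export
viterbi_local <- function(model, seq) {
  s <- check_scan_seq(seq)
  p <- phmm_log_par(model)
  r <- phmm_viterbi_cpp(p$lom, p$loi, p$ltm, p$lti, p$ltd, encode_nt(s))
  structure(list(
    log_odds = r$score / log(2),
    nats = r$score,
    best_path = r$path,
    model_span = c(r$model_start, r$model_end),
    seq_span = c(r$seq_start, r$seq_end),
    col_of_pos = r$col_of_pos
  ), class = "phmm_score")
}

#' @export
print.phmm_score <- function(x, ...) {
  cat(sprintf("local HMM alignment: %.2f bits, model %s-%s, seq %s-%s\n",
              x$log_odds, x$model_span[1], x$model_span[2],
              x$seq_span[1], x$seq_span[2]))
  invisible(x)
}

#' Local forward score of a sequence against a profile HMM
#'
#' Total log-odds over all local paths (including the empty alignment),
#' in bits; always at least the Viterbi score.
#'
#' @inheritParams viterbi_local
#' @return numeric scalar (bits).
#' @export
forward_local <- function(model, seq) {
  s <- check_scan_seq(seq)
  p <- phmm_log_par(model)
  phmm_forward_cpp(p$lom, p$loi, p$ltm, p$lti, p$ltd, encode_nt(s)) / log(2)
}

#' Serialise a profile HMM to versioned JSON
#'
#' @param model a `profile_hmm`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(model, path) {
  obj <- list(format = "rnascout-phmm", version = 1L,
              n_match = model$n_match,
              match_emissions = model$match_emissions,
              insert_emissions = as.list(model$insert_emissions),
              transitions = model$transitions,
              background = as.list(model$background),
              column_map = model$column_map,
              pseudocount = model$pseudocount,
              gap_fraction_threshold = model$gap_fraction_threshold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a profile HMM from JSON written by [write_profile()]
#'
#' @param path file path.
#' @return a `profile_hmm`.
#' @export
read_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "rnascout-phmm"))
    stop("not an rnascout profile HMM file", call. = FALSE)
  me <- matrix(unlist(obj$match_emissions), ncol = 4,
               dimnames = list(NULL, NT))
  fix <- function(m, nm) {
    m <- matrix(unlist(m), ncol = length(nm))
    colnames(m) <- nm
    m
  }
  structure(list(
    n_match = obj$n_match,
    match_emissions = me,
    insert_emissions = unlist(obj$insert_emissions)[NT],
    transitions = list(from_m = fix(obj$transitions$from_m, c("M", "I", "D")),
                       from_i = fix(obj$transitions$from_i, c("M", "I")),
                       from_d = fix(obj$transitions$from_d, c("M", "D"))),
    background = unlist(obj$background)[NT],
    column_map = obj$column_map,
    pseudocount = obj$pseudocount,
    gap_fraction_threshold = obj$gap_fraction_threshold
  ), class = "profile_hmm")
}
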