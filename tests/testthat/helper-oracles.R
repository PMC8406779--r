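# Independent oracles: exhaustive enumerations kept deliberately free of
# the package's DP implementations.

NT4 <- c("A", "C", "G", "T")

rc_chr <- function(s) {
  chartr("ACGTU", "TGCAA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# ---- profile-HMM path enumeration -----------------------------------------

# All legal local path scores (nats) of `seq` against `model`:
# entry into any match column, exit from any match column, moves
# M->{M,I,D}, I->{I,M}, D->{D,M}; the empty alignment scores 0.
enum_phmm_scores <- function(model, seq) {
  n <- model$n_match
  lbg <- log(model$background)
  lom <- log(model$match_emissions) - matrix(lbg, n, 4, byrow = TRUE)
  loi <- log(model$insert_emissions) - lbg
  ltm <- log(model$transitions$from_m)
  lti <- log(model$transitions$from_i)
  ltd <- log(model$transitions$from_d)
  x <- match(strsplit(seq, "")[[1]], NT4)
  L <- length(x)
  emM <- function(i, j) if (is.na(x[i])) 0 else lom[j, x[i]]
  emI <- function(i) if (is.na(x[i])) 0 else loi[x[i]]

  scores <- 0  # empty alignment
  rec <- function(i, j, state, acc) {
    if (state == "M") scores <<- c(scores, acc)
    if (j >= n) return(invisible())
    if (state == "M") {
      if (i < L) {
        rec(i + 1, j + 1, "M", acc + ltm[j, "M"] + emM(i + 1, j + 1))
        rec(i + 1, j, "I", acc + ltm[j, "I"] + emI(i + 1))
      }
      rec(i, j + 1, "D", acc + ltm[j, "D"])
    } else if (state == "I") {
      if (i < L) {
        rec(i + 1, j, "I", acc + lti[j, "I"] + emI(i + 1))
        rec(i + 1, j + 1, "M", acc + lti[j, "M"] + emM(i + 1, j + 1))
      }
    } else {
      rec(i, j + 1, "D", acc + ltd[j, "D"])
      if (i < L) rec(i + 1, j + 1, "M", acc + ltd[j, "M"] + emM(i + 1, j + 1))
    }
  }
  for (s in seq_len(L))
    for (k in seq_len(n))
      rec(s, k, "M", emM(s, k))
  scores
}

lse <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# a tiny profile built from a random gapped alignment
random_tiny_model <- function(ncol_aln = 4, nseq = 3, gap_p = 0.15) {
  repeat {
    rows <- vapply(seq_len(nseq), function(i) {
      v <- sample(NT4, ncol_aln, replace = TRUE)
      g <- stats::runif(ncol_aln) < gap_p
      v[g] <- "-"
      paste(v, collapse = "")
    }, character(1))
    aln <- try(new_alignment(stats::setNames(rows, paste0("s", 1:nseq))),
               silent = TRUE)
    if (inherits(aln, "try-error")) next
    m <- try(build_profile(aln), silent = TRUE)
    if (!inherits(m, "try-error") && m$n_match >= 2) return(m)
  }
}

# ---- structure enumeration ------------------------------------------------

# every valid pseudoknot-free pair set over 1..n
enum_structures <- function(seqv, min_loop = 3) {
  ps <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                        c("A", "C", "G", "U")))
  ps["G", "C"] <- ps["C", "G"] <- 3
  ps["A", "U"] <- ps["U", "A"] <- 2
  ps["G", "U"] <- ps["U", "G"] <- 1
  pairable <- function(i, j) ps[seqv[i], seqv[j]] > 0
  rec <- function(i, j) {
    if (i >= j || j - i <= min_loop)
      return(list(matrix(integer(0), 0, 2)))
    out <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (!pairable(i, k)) next
      inner <- rec(i + 1, k - 1)
      rest <- if (k < j) rec(k + 1, j) else
        list(matrix(integer(0), 0, 2))
      for (a in inner)
        for (b in rest)
          out <- c(out, list(rbind(matrix(c(i, k), 1, 2), a, b)))
    }
    out
  }
  rec(1, length(seqv))
}

score_structure <- function(pairs, seqv, stack_bonus = 1) {
  if (nrow(pairs) == 0) return(0)
  ps <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                        c("A", "C", "G", "U")))
  ps["G", "C"] <- ps["C", "G"] <- 3
  ps["A", "U"] <- ps["U", "A"] <- 2
  ps["G", "U"] <- ps["U", "G"] <- 1
  base <- sum(ps[cbind(seqv[pairs[, 1]], seqv[pairs[, 2]])])
  key <- paste(pairs[, 1], pairs[, 2])
  base + stack_bonus * sum(paste(pairs[, 1] + 1, pairs[, 2] - 1) %in% key)
}

best_structure_score <- function(seq, min_loop = 3) {
  seqv <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  max(vapply(enum_structures(seqv, min_loop), score_structure, numeric(1),
             seqv = seqv))
}

# ---- misc oracles ---------------------------------------------------------

# maximal T-runs by regex (independent of the rle-based implementation)
regex_t_tracks <- function(seq, min_t = 4, max_t = NULL) {
  m <- gregexpr(sprintf("T{%d,}", min_t), seq)[[1]]
  if (m[1] == -1)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  len <- attr(m, "match.length")
  keep <- if (is.null(max_t)) rep(TRUE, length(m)) else len <= max_t
  data.frame(start = as.integer(m[keep]),
             end = as.integer(m[keep] + len[keep] - 1L),
             length = as.integer(len[keep]))
}

# brute-force amplicon search over all substrings
brute_amplicon_length <- function(template, fwd, rev) {
  n <- nchar(template)
  wf <- nchar(fwd)
  fs <- which(vapply(seq_len(n - wf + 1), function(i)
    substr(template, i, i + wf - 1) == fwd, logical(1)))
  if (!length(fs)) return(NULL)
  f1 <- fs[1]
  rcsite <- rc_chr(rev)
  wr <- nchar(rcsite)
  rs <- which(vapply(seq_len(n - wr + 1), function(i)
    substr(template, i, i + wr - 1) == rcsite, logical(1)))
  rs <- rs[rs >= f1 & rs + wr - 1 >= f1 + wf - 1]
  if (!length(rs)) return(NULL)
  min(rs + wr - 1) - f1 + 1L
}
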