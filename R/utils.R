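# Shared nucleotide helpers.

NT <- c("A", "C", "G", "T")

#' Normalise a nucleotide string
#'
#' Uppercases and converts U to T (DNA alphabet is used internally
#' throughout; RNA is produced only at the folding step).
#'
#' @param x character vector of sequences.
#' @return normalised character vector.
#' @keywords internal
norm_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

assert_alphabet <- function(x, allowed, what = "sequence") {
  bad <- gsub(paste0("[", paste(allowed, collapse = ""), "]"), "", x)
  if (any(nchar(bad) > 0)) {
    stop(sprintf("invalid characters in %s: '%s'", what,
                 substr(bad[nchar(bad) > 0][1], 1, 10)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Reverse complement of a DNA string
#'
#' @param x character scalar or vector of DNA strings.
#' @return reverse complement as character.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# integer encoding A=0 C=1 G=2 T/U=3 N=4 (for the C++ kernels)
encode_nt <- function(x) {
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  m <- match(v, c("A", "C", "G", "T", "N"))
  if (anyNA(m)) stop("sequence contains characters outside {A,C,G,T,N}",
                     call. = FALSE)
  m - 1L
}

#' Sample a random DNA sequence with a given GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2. With
#' `max_t_run` set, any run of T reaching that length is broken by
#' resampling the offending base from A/C/G, so the result carries no
#' T-run of `max_t_run` or longer (used to keep synthetic backgrounds
#' free of spurious Pol III terminators).
#'
#' @param n sequence length.
#' @param gc GC fraction in (0, 1).
#' @param max_t_run if not NULL, forbid T-runs of this length or longer.
#' @return a character scalar of length-n DNA.
#' @export
random_dna <- function(n, gc = 0.43, max_t_run = NULL) {
  stopifnot(n >= 0, gc > 0, gc < 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  v <- sample(NT, n, replace = TRUE, prob = p)
  if (!is.null(max_t_run) && n >= max_t_run) {
    run <- 0L
    for (i in seq_len(n)) {
      if (v[i] == "T") {
        run <- run + 1L
        if (run >= max_t_run) {
          v[i] <- sample(c("A", "C", "G"), 1)
          run <- 0L
        }
      } else run <- 0L
    }
  }
  paste(v, collapse = "")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
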