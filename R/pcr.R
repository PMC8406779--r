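# In-silico PCR (amplicon prediction from primer pairs) and the
# semi-quantitative RT-PCR dilution arithmetic: serial base^k dilutions
# read at the least saturated point of a housekeeping reference.

#' Predict the amplicon of a primer pair on a template
#'
#' Matches the forward primer on the sense strand (leftmost site when
#' several exist) and pairs it with the nearest downstream reverse-
#' primer site (the reverse complement of the reverse primer on the
#' sense strand). With `max_mismatch > 0`, mismatches are allowed except
#' in the 3'-terminal 3 nt of either primer, which must match exactly.
#'
#' @param template sense-strand DNA string.
#' @param fwd,rev primer sequences 5'->3' (at least 10 nt, A/C/G/T).
#' @param max_mismatch mismatches tolerated per primer (default 0).
#' @param fwd_name,rev_name primer labels carried into the result.
#' @return a list `(fwd_name, rev_name, start, end, length)` of class
#'   `amplicon` (1-based inclusive on the template), or `NULL` when no
#'   orientation-consistent site pair exists.
#' @export
find_amplicon <- function(template, fwd, rev, max_mismatch = 0,
                          fwd_name = "fwd", rev_name = "rev") {
  template <- norm_dna(template)
  if (!nzchar(template)) stop("empty template", call. = FALSE)
  check_primer <- function(p, what) {
    p <- norm_dna(p)
    if (nchar(p) < 10) stop(what, " primer shorter than 10 nt",
                            call. = FALSE)
    assert_alphabet(p, NT, paste(what, "primer"))
    p
  }
  fwd <- check_primer(fwd, "forward")
  rev <- check_primer(rev, "reverse")

  tmpl <- Biostrings::DNAString(template)
  site_hits <- function(pattern) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), tmpl,
                                  max.mismatch = max_mismatch)
    data.frame(start = Biostrings::start(m), end = Biostrings::end(m))
  }
  three_prime_exact <- function(df, pattern, at_start) {
    if (max_mismatch == 0 || nrow(df) == 0) return(df)
    w <- nchar(pattern)
    keep <- vapply(seq_len(nrow(df)), function(k) {
      if (at_start) {
        substr(template, df$start[k], df$start[k] + 2) ==
          substr(pattern, 1, 3)
      } else {
        substr(template, df$end[k] - 2, df$end[k]) ==
          substr(pattern, w - 2, w)
      }
    }, logical(1))
    df[keep, , drop = FALSE]
  }
  f <- three_prime_exact(site_hits(fwd), fwd, at_start = FALSE)
  if (nrow(f) == 0) return(NULL)
  if (nrow(f) > 1)
    message("multiple forward-primer sites; using the leftmost")
  fs <- f$start[1]; fe <- f$end[1]

  rc <- revcomp(rev)
  # the reverse primer's 3' end maps to the START of its rc site
  r <- three_prime_exact(site_hits(rc), rc, at_start = TRUE)
  r <- r[r$start >= fs & r$end >= fe, , drop = FALSE]
  if (nrow(r) == 0) return(NULL)
  re <- min(r$end)
  structure(list(fwd_name = fwd_name, rev_name = rev_name,
                 start = fs, end = re, length = re - fs + 1L),
            class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("Amplicon %s/%s: %d-%d (%d nt)\n", x$fwd_name, x$rev_name,
              x$start, x$end, x$length))
  invisible(x)
}

#' Read primers from FASTA or a two-column TSV
#'
#' @param path file path. FASTA records or `name<TAB>sequence` lines.
#' @return named character vector of primer sequences.
#' @export
read_primers <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, ">")) {
    x <- Biostrings::readBStringSet(path)
    stats::setNames(norm_dna(as.character(x)), names(x))
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("name", "seq"),
                            stringsAsFactors = FALSE)
    stats::setNames(norm_dna(df$seq), df$name)
  }
}

#' Construct a serial-dilution intensity series
#'
#' Band intensities of one gene in one sample across a base^k dilution
#' ladder (base 5 in the classical protocol).
#'
#' @param sample_id sample label.
#' @param exponents strictly increasing dilution exponents k (dilution
#'   factor base^k).
#' @param intensities nonnegative finite band intensities, one per
#'   exponent.
#' @param base dilution factor base (default 5).
#' @param saturation_threshold intensity at or above which a band is
#'   considered saturated (default 0.9, on a detector scale of 1).
#' @return an object of class `dilution_series`.
#' @export
dilution_series <- function(sample_id, exponents, intensities, base = 5,
                            saturation_threshold = 0.9) {
  exponents <- as.integer(exponents)
  if (length(exponents) != length(intensities))
    stop("exponents and intensities differ in length", call. = FALSE)
  if (any(diff(exponents) <= 0))
    stop("exponents must be strictly increasing", call. = FALSE)
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and nonnegative", call. = FALSE)
  structure(list(sample_id = sample_id, base = base,
                 exponents = exponents, intensities = intensities,
                 saturation_threshold = saturation_threshold),
            class = "dilution_series")
}

#' Least saturated usable dilution of a series
#'
#' The smallest exponent whose band is detectable but not saturated
#' (0 < intensity < saturation threshold).
#'
#' @param series a [dilution_series()].
#' @return integer exponent.
#' @export
least_saturated_dilution <- function(series) {
  if (length(series$exponents) < 2)
    stop("need at least 2 dilution points", call. = FALSE)
  ok <- series$intensities > 0 &
    series$intensities < series$saturation_threshold
  if (!any(ok))
    stop("no usable dilution: all bands saturated or absent",
         call. = FALSE)
  min(series$exponents[ok])
}

#' Relative expression of a target against a reference series
#'
#' At the reference's least saturated dilution exponent e, the ratio of
#' the target's band intensity to the reference's. Both series must
#' share the dilution base, and the target must have a measurement at
#' e (no interpolation is attempted).
#'
#' @param target,reference [dilution_series()] objects from the same
#'   cDNA sample.
#' @return a list `(target_over_reference, chosen_exponent,
#'   reference_gene)` of class `relative_expression`.
#' @export
relative_expression <- function(target, reference) {
  if (target$base != reference$base)
    stop("series have different dilution bases", call. = FALSE)
  e <- least_saturated_dilution(reference)
  ti <- match(e, target$exponents)
  if (is.na(ti))
    stop(sprintf("target has no measurement at exponent %d; refusing to
 interpolate", e), call. = FALSE)
  ri <- match(e, reference$exponents)
  structure(list(
    target_over_reference =
      target$intensities[ti] / reference$intensities[ri],
    chosen_exponent = e,
    reference_gene = reference$sample_id
  ), class = "relative_expression")
}

#' Cross-sample abundance factor from dilution exponents
#'
#' Two samples read at reference exponents e1 and e2 with equal band
#' intensities differ in template abundance by base^(e1 - e2).
#'
#' @param e1,e2 reference dilution exponents of the two samples.
#' @param base dilution factor base (default 5).
#' @return numeric factor.
#' @export
dilution_scale_factor <- function(e1, e2, base = 5) {
  base^(e1 - e2)
}

#' Read band intensities from CSV
#'
#' Expects columns `sample`, `gene`, `exponent`, `intensity` and builds
#' one [dilution_series()] per (sample, gene).
#'
#' @param path CSV file path.
#' @param base,saturation_threshold passed to [dilution_series()].
#' @return nested list: `x[[sample]][[gene]]` is a `dilution_series`.
#' @export
read_band_intensities <- function(path, base = 5,
                                  saturation_threshold = 0.9) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "gene", "exponent", "intensity") %in%
                  names(df)))
  out <- list()
  for (s in unique(df$sample)) {
    out[[s]] <- list()
    for (g in unique(df$gene[df$sample == s])) {
      sub <- df[df$sample == s & df$gene == g, ]
      sub <- sub[order(sub$exponent), ]
      out[[s]][[g]] <- dilution_series(
        sprintf("%s:%s", s, g), sub$exponent, sub$intensity,
        base = base, saturation_threshold = saturation_threshold)
    }
  }
  out
}
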