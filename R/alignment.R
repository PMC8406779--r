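# Multiple-alignment ingestion for profile-HMM training.

#' Read a nucleotide multiple alignment
#'
#' Reads an aligned FASTA file or a minimal Stockholm file (header line
#' `# STOCKHOLM 1.0`, `name sequence` records, terminating `//`).
#' Sequences are uppercased and U is normalised to T. All rows must have
#' equal length and at least two sequences are required.
#'
#' Stockholm records are parsed directly rather than through the
#' Biostrings multiple-alignment readers because training alignments may
#' mix T and U rows, which a single fixed alphabet would reject before
#' normalisation can run.
#'
#' @param path file path.
#' @param format `"auto"` (by extension / header sniffing), `"fasta"` or
#'   `"stockholm"`.
#' @return an object of class `msa_aln`: a list with `sequences` (named
#'   character vector of gapped rows) and `length` (number of columns).
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  rows <- if (format == "fasta") {
    x <- Biostrings::readBStringSet(path)
    stats::setNames(as.character(x), names(x))
  } else {
    ln <- readLines(path)
    ln <- ln[!grepl("^#", ln) & !grepl("^//", ln) & nzchar(trimws(ln))]
    if (length(ln) == 0) stop("no sequence records in Stockholm file",
                              call. = FALSE)
    parts <- strsplit(trimws(ln), "[[:space:]]+")
    bad <- lengths(parts) != 2
    if (any(bad)) stop("malformed Stockholm sequence line", call. = FALSE)
    seqs <- vapply(parts, `[`, character(1), 2)
    ids <- vapply(parts, `[`, character(1), 1)
    # interleaved records: concatenate blocks per id, preserving order
    tapply_order <- unique(ids)
    stats::setNames(
      vapply(tapply_order, function(id)
        paste(seqs[ids == id], collapse = ""), character(1)),
      tapply_order)
  }
  new_alignment(rows)
}

#' Construct an alignment object from gapped rows
#'
#' @param rows named character vector of equal-length gapped sequences.
#' @return an `msa_aln` object.
#' @export
new_alignment <- function(rows) {
  if (length(rows) < 2) stop("alignment needs at least 2 sequences",
                             call. = FALSE)
  rows <- norm_dna(rows)
  rows <- chartr(".", "-", rows)
  w <- unique(nchar(rows))
  if (length(w) != 1) stop("ragged alignment: rows differ in length",
                           call. = FALSE)
  assert_alphabet(rows, c("A", "C", "G", "T", "N", "-"), "alignment")
  if (is.null(names(rows))) names(rows) <- paste0("seq", seq_along(rows))
  structure(list(sequences = rows, length = w), class = "msa_aln")
}

# column-wise character matrix of the alignment
aln_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$sequences), "", fixed = TRUE))
}

#' @export
print.msa_aln <- function(x, ...) {
  cat(sprintf("Multiple alignment: %d sequences x %d columns\n",
              length(x$sequences), x$length))
  invisible(x)
}
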