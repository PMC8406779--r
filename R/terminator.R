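# Oligo-T track scanning, RNA Pol III terminator calls, and gene-model
# construction from a TSS to the first terminator. Runs of >= 4 T on the
# sense strand are efficient Pol III termination signals, so a gene body
# littered with internal tracks is implausible as a Pol III transcript.

#' Find maximal oligo-T tracks on the sense strand
#'
#' @param seq sense-strand nucleotide string.
#' @param min_t minimum run length (default 4).
#' @param max_t maximum run length, or `NULL` for no cap; maximal runs
#'   longer than `max_t` are excluded entirely (not truncated).
#' @return data frame with `start`, `end` (1-based inclusive), `length`,
#'   sorted by start.
#' @export
find_t_tracks <- function(seq, min_t = 4, max_t = NULL) {
  if (min_t < 1) stop("min_t must be >= 1", call. = FALSE)
  if (length(seq) != 1 || !nzchar(seq))
    stop("sequence must be nonempty", call. = FALSE)
  seq <- norm_dna(seq)
  r <- rle(strsplit(seq, "")[[1]] == "T")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_t
  if (!is.null(max_t)) keep <- keep & r$lengths <= max_t
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Call an RNA Pol III terminator in a downstream sequence
#'
#' Takes the first maximal T-run of at least `min_t`; when a second
#' qualifying run follows within `max_gap` non-T nucleotides the call is
#' a DOUBLE terminator carrying both track lengths.
#'
#' @param downstream sense-strand sequence downstream of a position of
#'   interest.
#' @param min_t minimum run length (default 4).
#' @param max_gap maximum non-T gap between the two runs of a DOUBLE
#'   call (default 3).
#' @return a list `(position, track_lengths, kind)` of class
#'   `terminator_call` with `position` the 1-based start of the first
#'   run in `downstream`, or `NULL` when no qualifying run exists.
#' @export
call_terminator <- function(downstream, min_t = 4, max_gap = 3) {
  tr <- find_t_tracks(downstream, min_t = min_t)
  if (nrow(tr) == 0) return(NULL)
  terminator_from_tracks(tr, 1L, max_gap)
}

# build a terminator_call from track row i of a track table
terminator_from_tracks <- function(tr, i, max_gap) {
  kind <- "SINGLE"
  lens <- tr$length[i]
  last <- tr$end[i]
  if (i < nrow(tr) && tr$start[i + 1] - tr$end[i] - 1L <= max_gap) {
    kind <- "DOUBLE"
    lens <- c(lens, tr$length[i + 1])
    last <- tr$end[i + 1]
  }
  structure(list(position = tr$start[i], end_position = last,
                 track_lengths = lens, kind = kind),
            class = "terminator_call")
}

#' Gene length between a TSS and a terminator start
#'
#' Inclusive distance between the +1 nucleotide and the first base of
#' the terminator, valid for either strand.
#'
#' @param tss genomic position of the +1 nucleotide.
#' @param terminator_start genomic position of the terminator's first T.
#' @return integer length in bp.
#' @export
gene_length <- function(tss, terminator_start) {
  abs(terminator_start - tss) + 1L
}

#' Extract the sense-strand sequence downstream of a TSS
#'
#' Includes the TSS nucleotide itself as position 1.
#'
#' @inheritParams extract_upstream
#' @param span number of bp to extract.
#' @return character scalar.
#' @export
extract_downstream <- function(genome, contig, tss, strand = "+",
                               span = 1000) {
  seqs <- load_genome(genome)
  s <- seqs[[contig]]
  if (is.null(s)) stop("unknown contig: ", contig, call. = FALSE)
  if (tss < 1 || tss > nchar(s))
    stop("TSS outside contig", call. = FALSE)
  if (strand == "+") {
    substr(s, tss, min(nchar(s), tss + span - 1))
  } else {
    revcomp(substr(s, max(1, tss - span + 1), tss))
  }
}

#' Build a gene model from a TSS to the first terminator
#'
#' Scans the sense strand downstream of the TSS for the first
#' terminator. With `require_double = TRUE` (the default) only a DOUBLE
#' call (two maximal T-runs within `max_gap`) terminates the gene:
#' isolated internal tracks are inventoried, not taken as the 3' end —
#' this matches loci whose gene body carries internal oligo-T tracks
#' upstream of a genuine double-track terminator. With
#' `require_double = FALSE` the first qualifying run of any kind is the
#' terminator.
#'
#' The internal-track inventory reports maximal runs strictly between
#' the TSS and the terminator: all runs of at least `min_t`, the subset
#' of length `min_t` to `max_internal_t` (the classical 4-5 T
#' termination signals), and those within the first 100 nt of the gene.
#' `pol3_plausible` is `TRUE` only when no internal run of at least
#' `min_t` exists.
#'
#' @inheritParams extract_upstream
#' @param search_span bp of sense strand scanned downstream of the TSS.
#' @param min_t minimum T-run length (default 4).
#' @param max_gap maximum gap within a DOUBLE terminator (default 3).
#' @param require_double see Details.
#' @param max_internal_t cap for the classical internal-track count
#'   (default 5).
#' @return an object of class `gene_model`.
#' @export
build_gene_model <- function(genome, contig, tss, strand = "+",
                             search_span = 1000, min_t = 4, max_gap = 3,
                             require_double = TRUE, max_internal_t = 5) {
  if (search_span < 1) stop("search_span must be >= 1", call. = FALSE)
  body <- extract_downstream(genome, contig, tss, strand, search_span)
  tr <- find_t_tracks(body, min_t = min_t)
  term <- NULL
  if (nrow(tr) > 0) {
    if (require_double) {
      if (nrow(tr) > 1) {
        gaps <- tr$start[-1] - tr$end[-nrow(tr)] - 1L
        k <- which(gaps <= max_gap)
        if (length(k)) term <- terminator_from_tracks(tr, k[1], max_gap)
      }
    } else {
      term <- terminator_from_tracks(tr, 1L, max_gap)
    }
  }
  if (is.null(term)) {
    message(sprintf("no terminator within %d bp of %s:%d(%s)",
                    search_span, contig, tss, strand))
    internal <- tr
    len <- NA_integer_
    term_genomic <- NA_integer_
  } else {
    internal <- tr[tr$end < term$position & tr$start > 1, , drop = FALSE]
    len <- gene_length(1L, term$position)
    term_genomic <- if (strand == "+") tss + term$position - 1L
                    else tss - term$position + 1L
    term$genomic_position <- term_genomic
  }
  internal$genomic_start <- if (strand == "+") tss + internal$start - 1L
                            else tss - internal$start + 1L
  internal$genomic_end <- if (strand == "+") tss + internal$end - 1L
                          else tss - internal$end + 1L
  n45 <- sum(internal$length <= max_internal_t)
  structure(list(
    contig = contig, tss = tss, strand = strand,
    terminator = term, length = len,
    internal_tracks = internal,
    n_internal = nrow(internal),
    n_internal_4to5 = n45,
    n_internal_first100 = sum(internal$start <= 100),
    pol3_plausible = nrow(internal) == 0,
    body = substr(body, 1, if (is.na(len)) nchar(body) else len)
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("Gene model %s:%d(%s)\n", x$contig, x$tss, x$strand))
  if (is.null(x$terminator)) {
    cat("  terminator: none found\n")
  } else {
    cat(sprintf("  terminator: %s T%s at gene position %d, length %d bp\n",
                x$terminator$kind,
                paste(x$terminator$track_lengths, collapse = "+"),
                x$terminator$position, x$length))
  }
  cat(sprintf(
    "  internal T-tracks: %d (%d of 4-5 T; %d in first 100 nt)\n",
    x$n_internal, x$n_internal_4to5, x$n_internal_first100))
  cat(sprintf("  Pol III transcription plausible: %s\n",
              x$pol3_plausible))
  invisible(x)
}

#' Write a gene model as GFF3
#'
#' Emits the gene feature with child `t_track` and `terminator`
#' features (1-based inclusive coordinates).
#'
#' @param gm a `gene_model`.
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(gm, path) {
  if (is.null(gm$terminator))
    stop("cannot write a gene model without a terminator", call. = FALSE)
  g_start <- min(gm$tss, gm$terminator$genomic_position)
  g_end <- max(gm$tss, gm$terminator$genomic_position)
  term_other <- gm$terminator$genomic_position +
    ifelse(gm$strand == "+", 1L, -1L) *
    (gm$terminator$end_position - gm$terminator$position)
  feats <- data.frame(
    start = c(g_start, pmin(gm$internal_tracks$genomic_start,
                            gm$internal_tracks$genomic_end),
              min(gm$terminator$genomic_position, term_other)),
    end = c(g_end, pmax(gm$internal_tracks$genomic_start,
                        gm$internal_tracks$genomic_end),
            max(gm$terminator$genomic_position, term_other)),
    type = c("gene", rep("t_track", nrow(gm$internal_tracks)),
             "terminator"))
  gr <- GenomicRanges::GRanges(
    seqnames = gm$contig,
    ranges = IRanges::IRanges(start = feats$start, end = feats$end),
    strand = gm$strand, type = feats$type,
    ID = c("gene1", sprintf("t_track%d", seq_len(nrow(gm$internal_tracks))),
           "terminator1"),
    Parent = c(NA, rep("gene1", nrow(gm$internal_tracks) + 1L)))
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
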