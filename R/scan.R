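# Windowed two-strand genome scanning with a profile HMM and the
# two-end model-coverage filter that separates full-length family
# members from one-ended spurious hits.

#' Scan configuration
#'
#' @param model optional `profile_hmm` used to derive defaults.
#' @param window window size in bp (default 3x the model's match length).
#' @param step step between window starts (default window / 2).
#' @param score_threshold minimum hit score in bits (default 30).
#' @param min_end_cov minimum bp of a hit aligned to match columns in
#'   *each* of the 5' and 3' model regions for [two_end_filter()];
#'   strictly greater-than is required (default 100).
#' @param five_prime_region,three_prime_region integer vectors of model
#'   match columns defining the model's 5' and 3' regions; default the
#'   first and last 35% of match columns.
#' @return a list of class `scan_config`.
#' @export
scan_config <- function(model = NULL, window = NULL, step = NULL,
                        score_threshold = 30, min_end_cov = 100,
                        five_prime_region = NULL,
                        three_prime_region = NULL) {
  n <- if (!is.null(model)) model$n_match else NULL
  if (is.null(window)) {
    if (is.null(n)) stop("supply either `model` or `window`", call. = FALSE)
    window <- 3L * n
  }
  if (is.null(step)) step <- max(1L, window %/% 2L)
  if (step > window) stop("step must not exceed window", call. = FALSE)
  if (min_end_cov < 1) stop("min_end_cov must be >= 1", call. = FALSE)
  if (is.null(five_prime_region) && !is.null(n))
    five_prime_region <- seq_len(ceiling(0.35 * n))
  if (is.null(three_prime_region) && !is.null(n))
    three_prime_region <- seq.int(n - ceiling(0.35 * n) + 1L, n)
  structure(list(window = as.integer(window), step = as.integer(step),
                 score_threshold = score_threshold,
                 min_end_cov = as.integer(min_end_cov),
                 five_prime_region = five_prime_region,
                 three_prime_region = three_prime_region),
            class = "scan_config")
}

# coverage (bp aligned to match columns) of a set of model columns
end_coverage <- function(col_of_pos, region) {
  sum(col_of_pos %in% region)
}

scan_one_strand <- function(model, seq_chr, contig, strand, contig_len, cfg) {
  L <- nchar(seq_chr)
  starts <- unique(c(seq.int(1L, max(1L, L - cfg$window + 1L), cfg$step),
                     max(1L, L - cfg$window + 1L)))
  hits <- list()
  for (ws in starts) {
    we <- min(L, ws + cfg$window - 1L)
    sc <- viterbi_local(model, substr(seq_chr, ws, we))
    if (sc$log_odds < cfg$score_threshold || is.na(sc$seq_span[1])) next
    s <- ws + sc$seq_span[1] - 1L
    e <- ws + sc$seq_span[2] - 1L
    # report on forward reference coordinates
    if (strand == "+") {
      gs <- s; ge <- e
    } else {
      gs <- contig_len - e + 1L; ge <- contig_len - s + 1L
    }
    cov <- sc$col_of_pos[sc$col_of_pos > 0]
    hits[[length(hits) + 1L]] <- list(
      contig = contig, start = gs, end = ge, strand = strand,
      log_odds = sc$log_odds,
      model_start = sc$model_span[1], model_end = sc$model_span[2],
      five_prime_cov = end_coverage(sc$col_of_pos, cfg$five_prime_region),
      three_prime_cov = end_coverage(sc$col_of_pos, cfg$three_prime_region),
      model_cov = list(sort(unique(cov))))
  }
  hits
}

hits_df <- function(hits) {
  if (length(hits) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      log_odds = numeric(), model_start = integer(),
                      model_end = integer(), five_prime_cov = integer(),
                      three_prime_cov = integer(),
                      model_cov = I(list()),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    contig = vapply(hits, `[[`, character(1), "contig"),
    start = vapply(hits, `[[`, integer(1), "start"),
    end = vapply(hits, `[[`, integer(1), "end"),
    strand = vapply(hits, `[[`, character(1), "strand"),
    log_odds = vapply(hits, `[[`, numeric(1), "log_odds"),
    model_start = vapply(hits, `[[`, integer(1), "model_start"),
    model_end = vapply(hits, `[[`, integer(1), "model_end"),
    five_prime_cov = vapply(hits, `[[`, integer(1), "five_prime_cov"),
    three_prime_cov = vapply(hits, `[[`, integer(1), "three_prime_cov"),
    stringsAsFactors = FALSE)
  df$model_cov <- I(lapply(hits, function(h) h$model_cov[[1]]))
  df
}

# merge same-strand hits overlapping by >= 1 bp, keeping the best score
merge_hits <- function(df) {
  if (nrow(df) <= 1) return(df)
  keep <- logical(nrow(df))
  for (grp in split(seq_len(nrow(df)),
                    paste(df$contig, df$strand))) {
    sub <- grp[order(df$start[grp])]
    cluster <- list()
    cur <- c(sub[1])
    cur_end <- df$end[sub[1]]
    for (i in sub[-1]) {
      if (df$start[i] <= cur_end) {
        cur <- c(cur, i)
        cur_end <- max(cur_end, df$end[i])
      } else {
        cluster[[length(cluster) + 1]] <- cur
        cur <- c(i); cur_end <- df$end[i]
      }
    }
    cluster[[length(cluster) + 1]] <- cur
    for (cl in cluster) keep[cl[which.max(df$log_odds[cl])]] <- TRUE
  }
  df[keep, , drop = FALSE]
}

#' Scan a genome on both strands with a profile HMM
#'
#' Windows of `cfg$window` bp (stepped by `cfg$step`) on both strands are
#' aligned locally to the model; windows at or above the bit-score
#' threshold become hits. The reverse strand is scanned on the reverse
#' complement and hits are reported on forward-reference coordinates.
#' Overlapping same-strand hits are merged keeping the best score, and
#' hits are sorted by (contig, start).
#'
#' @param model a `profile_hmm`.
#' @param genome a named character vector of contig sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA file path.
#' @param cfg a [scan_config()].
#' @return a data frame of hits: contig, start, end (1-based inclusive),
#'   strand, log_odds (bits), model_start/model_end, five_prime_cov,
#'   three_prime_cov, model_cov (list column of matched model columns).
#' @export
scan_genome <- function(model, genome, cfg = scan_config(model)) {
  seqs <- load_genome(genome)
  if (length(seqs) == 0 || all(nchar(seqs) == 0))
    stop("empty genome", call. = FALSE)
  if (cfg$window < model$n_match)
    message("scan window is smaller than the model length; ",
            "full-length hits cannot be recovered")
  hits <- list()
  for (ctg in names(seqs)) {
    fwd <- seqs[[ctg]]
    L <- nchar(fwd)
    hits <- c(hits,
              scan_one_strand(model, fwd, ctg, "+", L, cfg),
              scan_one_strand(model, revcomp(fwd), ctg, "-", L, cfg))
  }
  df <- merge_hits(hits_df(hits))
  df[order(df$contig, df$start), , drop = FALSE]
}

#' Retain hits covering both model ends
#'
#' Keeps hits whose aligned coverage of the model's 5' region and of its
#' 3' region are both strictly greater than `cfg$min_end_cov` bp. This is
#' the filter that separates full-length family candidates from
#' one-ended spurious matches.
#'
#' @param hits data frame from [scan_genome()].
#' @param cfg a [scan_config()].
#' @return the filtered data frame (order preserved).
#' @export
two_end_filter <- function(hits, cfg) {
  hits[hits$five_prime_cov > cfg$min_end_cov &
         hits$three_prime_cov > cfg$min_end_cov, , drop = FALSE]
}

#' Load a genome into a named character vector
#'
#' @param genome named character vector, `DNAStringSet`, or FASTA path.
#' @return named character vector of uppercase contig sequences.
#' @export
load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome) &&
      !grepl("^[ACGTUNacgtun]+$", genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "XStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  if (is.null(names(genome)))
    names(genome) <- paste0("contig", seq_along(genome))
  # strip any FASTA description after the first whitespace
  names(genome) <- sub("\\s.*$", "", names(genome))
  norm_dna(genome)
}

#' Write hits as BED6 plus a coverage TSV
#'
#' BED intervals are 0-based half-open with score = bits x 100 clamped
#' to 0-1000; the companion TSV (same basename, `.tsv`) carries the
#' model spans and end coverages.
#'
#' @param hits data frame from [scan_genome()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = hits$contig,
    ranges = IRanges::IRanges(start = hits$start, end = hits$end),
    strand = hits$strand,
    score = pmin(1000, pmax(0, round(hits$log_odds * 100))),
    name = sprintf("hit_%d", seq_len(nrow(hits))))
  rtracklayer::export(gr, path, format = "BED")
  tsv <- hits[, c("contig", "start", "end", "strand", "log_odds",
                  "model_start", "model_end", "five_prime_cov",
                  "three_prime_cov")]
  utils::write.table(tsv, sub("\\.bed$", ".tsv", path), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
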