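test_that("make_family is deterministic and honours the zero-mutation limit", {
  a1 <- make_family(5, seed_length = 60, substitution_rate = 0.1,
                    indel_rate = 0.02, seed = 77)
  a2 <- make_family(5, seed_length = 60, substitution_rate = 0.1,
                    indel_rate = 0.02, seed = 77)
  expect_identical(a1, a2)

  a0 <- make_family(4, seed_length = 50, substitution_rate = 0,
                    indel_rate = 0, seed = 1)
  expect_true(all(a0$sequences == a0$seed_seq))
  expect_error(make_family(1, 50), "n_members")
})

test_that("pairwise identity matches the substitution-model expectation", {
  s <- 0.1
  aln <- make_family(10, seed_length = 400, substitution_rate = s,
                     indel_rate = 0, seed = 123)
  M <- do.call(rbind, strsplit(unname(aln$sequences), ""))
  pairs <- utils::combn(nrow(M), 2)
  ids <- apply(pairs, 2, function(p) mean(M[p[1], ] == M[p[2], ]))
  # P(match) = (1-s)^2 + s^2/3 under independent mutation to a
  # uniformly chosen different base
  expected <- (1 - s)^2 + s^2 / 3
  se <- sqrt(expected * (1 - expected) / ncol(M))
  expect_lt(abs(mean(ids) - expected), 3 * se)
})

test_that("cassette construction identities hold and truth maps to the genome", {
  set.seed(55)
  cs <- make_cassette()
  sg <- make_genome(list(cs), contig_len = 1500)
  tr <- sg$truth
  pse <- tr[tr$type == "PSE", ]
  tata <- tr[tr$type == "TATA", ]
  tss <- tr[tr$type == "TSS", ]
  gene <- tr[tr$type == "gene", ]
  expect_equal(tata$start - pse$end - 1, 8)
  expect_equal(tss$start - tata$end - 1, 18)
  expect_equal(gene$end - gene$start + 1, 404)
  # implanted element sequences match their specification exactly
  g <- sg$sequences[[pse$contig]]
  expect_equal(substr(g, pse$start, pse$end), default_pse_consensus())
  expect_equal(substr(g, tata$start, tata$end), default_tata_consensus())
  expect_equal(substr(g, tss$start, gene$end), cs$gene_seq)
})

test_that("minus-strand truth mirrors coordinates consistently", {
  set.seed(56)
  cs <- make_cassette(cassette_spec(strand = "-"))
  sg <- make_genome(list(cs), contig_len = 1500)
  tr <- sg$truth
  pse <- tr[tr$type == "PSE", ]
  tata <- tr[tr$type == "TATA", ]
  tss <- tr[tr$type == "TSS", ]
  expect_equal(pse$start - tata$end - 1, 8)
  expect_equal(tata$start - tss$start - 1, 18)
  g <- sg$sequences[[pse$contig]]
  expect_equal(revcomp(substr(g, pse$start, pse$end)),
               default_pse_consensus())
})

test_that("generator output re-read from disk reproduces the in-memory truth", {
  set.seed(57)
  cs <- make_cassette()
  sg <- make_genome(list(cs), contig_len = 1200)
  fa <- tempfile(fileext = ".fa")
  gff <- tempfile(fileext = ".gff3")
  write_genome(sg, fa, gff)
  back <- load_genome(fa)
  expect_identical(back, sg$sequences)
  gr <- rtracklayer::import(gff)
  expect_equal(length(gr), nrow(sg$truth))
  got <- data.frame(start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    type = as.character(gr$type))
  got <- got[order(got$start, got$type), ]
  want <- sg$truth[order(sg$truth$start, sg$truth$type),
                   c("start", "end", "type")]
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$type, want$type)
})

test_that("implant flanks carry no oligo-T or oligo-A runs", {
  set.seed(58)
  cs <- make_cassette()
  sg <- make_genome(list(cs), contig_len = 1500)
  cass <- sg$truth[sg$truth$type == "cassette", ]
  g <- sg$sequences[[cass$contig]]
  left <- substr(g, max(1, cass$start - 50), cass$start - 1)
  right <- substr(g, cass$end + 1, min(nchar(g), cass$end + 50))
  expect_false(grepl("TTTT|AAAA", left))
  expect_false(grepl("TTTT|AAAA", right))
  # and the gene body carries exactly the specified runs
  body <- substr(g, cass$start + cs$tss_offset - 1,
                 cass$start + cs$tss_offset + 402)
  tr <- find_t_tracks(body, 4)
  expect_equal(tr$start, cs$internal_t_tracks$offset)
})
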