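test_that("find_t_tracks reports maximal runs with min/max caps", {
  tr <- find_t_tracks("AATTTTA", min_t = 4)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$start, 3)
  expect_equal(tr$length, 4)
  # a maximal run of 6 is excluded entirely by max_t = 5
  expect_equal(nrow(find_t_tracks("TTTTTT", min_t = 4, max_t = 5)), 0)
  tr2 <- find_t_tracks("TTTTATTTT", min_t = 4)
  expect_equal(nrow(tr2), 2)
  expect_equal(tr2$start, c(1, 6))
  expect_error(find_t_tracks("ACGT", min_t = 0), "min_t")
  expect_error(find_t_tracks(""), "nonempty")
})

test_that("find_t_tracks equals the regex maximal-run oracle on random sequences", {
  set.seed(77)
  for (rep in 1:1000) {
    s <- random_dna(200, gc = sample(c(0.3, 0.43, 0.6), 1))
    mt <- sample(3:5, 1)
    expect_identical(find_t_tracks(s, min_t = mt), regex_t_tracks(s, mt))
  }
})

test_that("call_terminator distinguishes double, single and absent", {
  d <- call_terminator("TTTTGTTTTTTAAA")
  expect_equal(d$kind, "DOUBLE")
  expect_equal(d$track_lengths, c(4L, 6L))
  expect_equal(d$position, 1L)
  s <- call_terminator("AATTTTAAAAACCCGGTTTT")
  expect_equal(s$kind, "SINGLE")
  expect_equal(s$track_lengths, 4L)
  expect_null(call_terminator("TTAT"))
})

test_that("the canonical cassette yields a 404-bp gene with five internal tracks", {
  set.seed(8)
  cs <- make_cassette()
  gnm <- stats::setNames(cs$sequence, "c")
  gm <- build_gene_model(gnm, "c", cs$tss_offset, "+", search_span = 450)
  expect_equal(gm$length, 404L)
  expect_equal(gm$terminator$kind, "DOUBLE")
  expect_equal(gm$terminator$track_lengths, c(4L, 6L))
  expect_equal(gm$n_internal, 5L)
  expect_equal(gm$n_internal_4to5, 5L)
  expect_equal(gm$n_internal_first100, 4L)
  expect_false(gm$pol3_plausible)
  # the implanted inventory is recovered exactly
  expect_equal(gm$internal_tracks$start, cs$internal_t_tracks$offset)
  expect_equal(gm$internal_tracks$length, cs$internal_t_tracks$length)
})

test_that("a gene without internal tracks is Pol III-plausible", {
  set.seed(9)
  no_tracks <- data.frame(offset = integer(0), length = integer(0))
  cs <- make_cassette(cassette_spec(internal_t_tracks = no_tracks))
  gm <- build_gene_model(stats::setNames(cs$sequence, "c"), "c",
                         cs$tss_offset, "+", search_span = 450)
  expect_equal(gm$length, 404L)
  expect_equal(gm$n_internal, 0L)
  expect_true(gm$pol3_plausible)
})

test_that("gene length is strand-consistent", {
  set.seed(10)
  cs <- make_cassette(cassette_spec(strand = "-"))
  sg <- make_genome(list(cs), contig_len = 1500)
  tss <- sg$truth[sg$truth$type == "TSS", ]
  gm <- build_gene_model(sg$sequences, tss$contig, tss$start, "-",
                         search_span = 450)
  expect_equal(gm$length, 404L)
  expect_equal(gm$terminator$track_lengths, c(4L, 6L))
  expect_equal(gm$n_internal, 5L)
})

test_that("without a terminator in range the model reports it honestly", {
  gnm <- stats::setNames(paste0("A", strrep("CGA", 200)), "c")
  expect_message(gm <- build_gene_model(gnm, "c", 1, "+",
                                        search_span = 300),
                 "no terminator")
  expect_true(is.na(gm$length))
  expect_null(gm$terminator)
})

test_that("gene models export as GFF3 with child features", {
  set.seed(12)
  cs <- make_cassette()
  gm <- build_gene_model(stats::setNames(cs$sequence, "c"), "c",
                         cs$tss_offset, "+", search_span = 450)
  f <- tempfile(fileext = ".gff3")
  write_gene_gff3(gm, f)
  gr <- rtracklayer::import(f)
  expect_equal(sum(gr$type == "gene"), 1)
  expect_equal(sum(gr$type == "t_track"), 5)
  expect_equal(sum(gr$type == "terminator"), 1)
  gene <- gr[gr$type == "gene"]
  expect_equal(GenomicRanges::width(gene), 404)
})
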