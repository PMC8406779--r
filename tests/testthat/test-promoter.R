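test_that("find_element locates a consensus, honours the floor, breaks ties rightmost", {
  pwm <- pwm_from_consensus("PSE", default_pse_consensus())
  set.seed(21)
  pad <- random_dna(30, 0.5)
  up <- paste0(pad, default_pse_consensus(), random_dna(20, 0.5))
  hit <- find_element(up, pwm)
  expect_equal(hit$start, 31)
  expect_equal(hit$score, 1.0, tolerance = 1e-12)

  gc_pwm <- pwm_from_consensus("GC", "GCGCGCGC", min_score = 0.8)
  expect_null(find_element(strrep("A", 40), gc_pwm))

  # two perfect copies: rightmost reported
  up2 <- paste0(default_tata_consensus(), strrep("C", 10),
                default_tata_consensus(), strrep("C", 5))
  tata <- pwm_from_consensus("TATA", default_tata_consensus())
  expect_equal(find_element(up2, tata)$start, 19)
  expect_error(find_element("ACGT", pwm), "shorter")
})

test_that("the canonical cassette annotates with 8/18 spacing and a Pol III verdict", {
  set.seed(31)
  cs <- make_cassette()
  gnm <- stats::setNames(cs$sequence, "c")
  up <- extract_upstream(gnm, "c", cs$tss_offset, "+", cs$tss_offset - 1)
  ann <- annotate_promoter(up)
  expect_equal(ann$pse_tata_spacer, 8L)
  expect_equal(ann$tata_tss_gap, 18L)
  expect_equal(ann$verdict, "POL3_TYPE")
  expect_equal(ann$tc_at, c(19L, 20L))

  # random upstream: nothing found
  set.seed(32)
  ann0 <- annotate_promoter(random_dna(100, 0.43))
  expect_equal(ann0$verdict, "NONE")
  expect_error(annotate_promoter(up, tss_offset = 1000), "outside")
})

test_that("a PSE + PSEB cassette without TATA is called Pol II-type", {
  set.seed(33)
  # a Pol II-type snRNA promoter: PSE without the TC dinucleotide at
  # 19-20, PSEB in place of the TATA box
  pse_pol2 <- paste0(substr(default_pse_consensus(), 1, 18), "GA",
                     substr(default_pse_consensus(), 21, 21))
  cs <- make_cassette(cassette_spec(pse_seq = pse_pol2,
                                    tata_seq = NULL,
                                    pseb_seq = default_pseb_consensus()))
  up <- extract_upstream(stats::setNames(cs$sequence, "c"), "c",
                         cs$tss_offset, "+", cs$tss_offset - 1)
  ann <- annotate_promoter(up)
  expect_null(ann$tata)
  expect_false(is.null(ann$pseb))
  expect_equal(ann$verdict, "POL2_TYPE")
})

test_that("polymerase classification follows the TC-dinucleotide rule", {
  pse_tc <- default_pse_consensus()      # TC at 19-20
  pse_ga <- paste0(substr(pse_tc, 1, 18), "GA",
                   substr(pse_tc, 21, 21))
  el <- function(seq) list(start = 1, end = nchar(seq), score = 1,
                           seq = seq)
  base <- structure(list(pse = el(pse_tc), tata = el("TATAAATG"),
                         pseb = NULL, pse_tata_spacer = 8L,
                         tata_tss_gap = 18L, spacer_ok = TRUE,
                         gap_ok = TRUE),
                    class = "promoter_annotation")
  expect_equal(classify_polymerase(base, pse_tc), "POL3_TYPE")

  pol2 <- base
  pol2$pse <- el(pse_ga); pol2$tata <- NULL
  pol2$pseb <- el(default_pseb_consensus())
  expect_equal(classify_polymerase(pol2, pse_ga), "POL2_TYPE")

  lone <- base
  lone$tata <- NULL; lone$pseb <- NULL
  expect_equal(classify_polymerase(lone, pse_tc), "AMBIGUOUS")
  none <- base; none$pse <- NULL
  expect_equal(classify_polymerase(none, ""), "NONE")
  # PSE too short to carry the TC position
  short <- base; short$pse <- el("ACGTACGTAC")
  expect_message(out <- classify_polymerase(short, "ACGTACGTAC"),
                 "AMBIGUOUS")
  expect_equal(out, "AMBIGUOUS")
})

test_that("implanted spacings are recovered exactly across seeded trials", {
  no_motifs <- data.frame(name = character(0), start = integer(0))
  ok <- 0L
  n_trials <- 400L
  for (s in seq_len(n_trials)) {
    set.seed(1000 + s)
    cs <- make_cassette(cassette_spec(motifs = no_motifs))
    up <- extract_upstream(stats::setNames(cs$sequence, "c"), "c",
                           cs$tss_offset, "+", cs$tss_offset - 1)
    ann <- annotate_promoter(up)
    if (identical(ann$pse_tata_spacer, 8L) &&
        identical(ann$tata_tss_gap, 18L) &&
        ann$verdict == "POL3_TYPE") ok <- ok + 1L
  }
  expect_gte(ok / n_trials, 0.99)
})

test_that("minus-strand cassettes annotate identically after strand extraction", {
  set.seed(41)
  cs_plus <- make_cassette(cassette_spec(strand = "+"))
  set.seed(41)
  cs_minus <- make_cassette(cassette_spec(strand = "-"))
  set.seed(51)
  sgp <- make_genome(list(cs_plus), contig_len = 1500)
  set.seed(51)
  sgm <- make_genome(list(cs_minus), contig_len = 1500)
  tss_p <- sgp$truth[sgp$truth$type == "TSS", ]
  tss_m <- sgm$truth[sgm$truth$type == "TSS", ]
  up_p <- extract_upstream(sgp$sequences, tss_p$contig, tss_p$start, "+",
                           55)
  up_m <- extract_upstream(sgm$sequences, tss_m$contig, tss_m$start, "-",
                           55)
  expect_identical(up_p, up_m)
  a_p <- annotate_promoter(up_p)
  a_m <- annotate_promoter(up_m)
  expect_identical(a_p$verdict, a_m$verdict)
  expect_identical(a_p$pse_tata_spacer, a_m$pse_tata_spacer)
  expect_identical(a_p$tata_tss_gap, a_m$tata_tss_gap)
})
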