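test_that("build_profile applies Laplace pseudocounts exactly", {
  aln <- new_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  m <- build_profile(aln, pseudocount = 1)
  expect_equal(m$n_match, 4)
  # hand-computed Laplace counts: (3+1)/(3+4) for the observed base
  expect_equal(unname(m$match_emissions[1, "A"]), 4 / 7)
  expect_equal(unname(m$match_emissions[2, "C"]), 4 / 7)
  expect_equal(unname(m$match_emissions[1, "G"]), 1 / 7)
  # single-column two-row case: (2+1)/(2+4)
  m2 <- build_profile(new_alignment(c(a = "A", b = "A")))
  expect_equal(m2$n_match, 1)
  expect_equal(unname(m2$match_emissions[1, "A"]), 0.5)
})

test_that("gap-heavy columns are excluded from match states", {
  aln <- new_alignment(c(a = "A-CG", b = "A-CG", c = "AAC-"))
  m <- build_profile(aln, gap_fraction_threshold = 0.5)
  # column 2 is gapped in 2/3 rows -> insert column
  expect_equal(m$column_map, c(1, 3, 4))
  expect_error(build_profile(new_alignment(c(a = "----", b = "----"))),
               "no match columns")
})

test_that("emission and transition rows are proper distributions", {
  set.seed(11)
  for (rep in 1:5) {
    m <- random_tiny_model(ncol_aln = 6, nseq = 4)
    expect_true(all(abs(rowSums(m$match_emissions) - 1) < 1e-9))
    expect_true(all(m$match_emissions > 0))
    expect_equal(sum(m$insert_emissions), 1, tolerance = 1e-9)
    expect_equal(sum(m$background), 1, tolerance = 1e-9)
    for (tr in m$transitions) {
      if (nrow(tr)) expect_true(all(abs(rowSums(tr) - 1) < 1e-9))
      expect_true(all(tr > 0))
    }
  }
})

test_that("Viterbi and forward agree with exhaustive path enumeration", {
  set.seed(101)
  for (rep in 1:25) {
    m <- random_tiny_model(ncol_aln = sample(2:4, 1), nseq = 3)
    seq <- random_dna(sample(1:6, 1), gc = 0.5)
    scores <- enum_phmm_scores(m, seq)
    v <- viterbi_local(m, seq)
    expect_equal(v$nats, max(scores), tolerance = 1e-9)
    expect_equal(forward_local(m, seq), lse(scores) / log(2),
                 tolerance = 1e-9)
  }
})

test_that("forward dominates Viterbi and both are deterministic", {
  set.seed(5)
  aln <- make_family(6, seed_length = 40, substitution_rate = 0.1,
                     indel_rate = 0.02, seed = 5)
  m <- build_profile(aln)
  s <- random_dna(60, 0.5)
  v1 <- viterbi_local(m, s)
  v2 <- viterbi_local(m, s)
  expect_identical(v1, v2)
  expect_gte(forward_local(m, s), v1$log_odds)
  # local-alignment floor: never below the empty alignment
  expect_gte(viterbi_local(m, random_dna(50, 0.5))$log_odds, 0)
  expect_error(viterbi_local(m, ""), "nonempty")
})

test_that("the consensus outscores every training row", {
  aln <- make_family(8, seed_length = 60, substitution_rate = 0.1,
                     indel_rate = 0, seed = 42)
  m <- build_profile(aln)
  cons <- consensus_seq(m)
  row_scores <- vapply(aln$sequences, function(r)
    viterbi_local(m, gsub("-", "", r))$log_odds, numeric(1))
  expect_gte(viterbi_local(m, cons)$log_odds, max(row_scores))
})

test_that("N residues score as background and huge pseudocounts flatten emissions", {
  aln <- make_family(4, seed_length = 20, substitution_rate = 0.05,
                     indel_rate = 0, seed = 3)
  m <- build_profile(aln)
  s <- gsub("-", "", aln$sequences[[1]])
  sN <- paste0(substr(s, 1, 10), "N", substr(s, 12, nchar(s)))
  expect_true(is.finite(viterbi_local(m, sN)$log_odds))
  m_flat <- build_profile(aln, pseudocount = 1e6)
  expect_true(all(abs(sweep(m_flat$match_emissions, 2,
                            m_flat$background)) < 1e-3))
})

test_that("profile JSON serialisation round-trips", {
  aln <- make_family(5, seed_length = 30, substitution_rate = 0.1,
                     indel_rate = 0.05, seed = 9)
  m <- build_profile(aln)
  f <- tempfile(fileext = ".json")
  write_profile(m, f)
  m2 <- read_profile(f)
  expect_equal(m2$match_emissions, m$match_emissions, tolerance = 1e-12)
  expect_equal(m2$transitions$from_m, m$transitions$from_m,
               tolerance = 1e-12)
  expect_equal(m2$column_map, m$column_map)
  s <- random_dna(40, 0.5)
  expect_equal(viterbi_local(m2, s)$nats, viterbi_local(m, s)$nats)
})
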