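test_that("fold_rna recovers the designed helix of a simple hairpin", {
  st <- fold_rna("GGGGAAAACCCC")
  # exhaustive enumeration gives the same optimum: the 4-pair GC helix
  expect_equal(st$score, best_structure_score("GGGGAAAACCCC"))
  expect_equal(nrow(st$pairs), 4)
  expect_equal(st$pairs[, "i"], 1:4, ignore_attr = TRUE)
  expect_equal(st$pairs[, "j"], 12:9, ignore_attr = TRUE)
  expect_equal(dotbracket(st), "((((....))))")

  st0 <- fold_rna("AAAAAAAA")
  expect_equal(nrow(st0$pairs), 0)
  expect_equal(st0$energy, 0)
  expect_error(fold_rna("ACGU"), "length >= 8")
})

test_that("fold_rna equals exhaustive structure enumeration up to 14 nt", {
  set.seed(202)
  for (rep in 1:40) {
    n <- sample(8:14, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
               collapse = "")
    expect_equal(fold_rna(s)$score, best_structure_score(s),
                 info = s)
  }
})

test_that("fold output always satisfies the structure invariants", {
  set.seed(203)
  for (rep in 1:20) {
    s <- random_dna(sample(20:80, 1), gc = 0.5)
    st <- fold_rna(s)
    # re-validating through the constructor enforces every invariant
    expect_silent(new_rna_structure(st$sequence, st$pairs))
    if (nrow(st$pairs))
      expect_true(all(st$pairs[, 2] - st$pairs[, 1] >= 4))
  }
})

test_that("folding is mirror-symmetric under sequence reversal", {
  # reversing the sequence maps pair (i, j) to (n-j+1, n-i+1) with the
  # bases swapped; the scoring is symmetric in the two bases, so the
  # optimum score is invariant (note reverse-complementation would not
  # be: a GU wobble maps to an unpairable AC)
  set.seed(204)
  for (rep in 1:10) {
    s <- random_dna(30, gc = 0.5)
    n <- nchar(s)
    st1 <- fold_rna(s)
    st2 <- fold_rna(paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    expect_equal(st1$score, st2$score)
    # pair (i, j) maps to (n-j+1, n-i+1) in the mirrored sequence and
    # must score identically there (pair sets can differ under ties)
    p1 <- st1$pairs
    m <- cbind(n - p1[, 2] + 1, n - p1[, 1] + 1)
    m <- m[order(m[, 1]), , drop = FALSE]
    v2 <- strsplit(st2$sequence, "")[[1]]
    expect_equal(score_structure(m, v2), st2$score)
  }
})

test_that("check_core detects closure, is window-monotone, and reads the GAUC variant", {
  # construct a closure: first 10 pair with last 10
  arm <- "GGAUCGCCGG"
  s <- paste0(arm, strrep("A", 12), rc_chr(arm))
  st <- fold_rna(s)
  cc <- check_core(st, end_window = 10)
  expect_true(cc$closed)
  expect_gte(cc$n_end_pairs, 4)
  expect_equal(cc$gauc_variant, "GAUC")

  open <- fold_rna("GGGGAAAACCCCAAAAAAAAAAAAAAAAA")
  expect_false(check_core(open, end_window = 4)$closed)

  prev <- -1
  for (w in c(5, 10, 15, 20)) {
    ne <- check_core(st, end_window = w)$n_end_pairs
    expect_gte(ne, prev)
    prev <- ne
  }

  set.seed(61)
  cs <- make_cassette()
  cc94 <- check_core(fold_rna(cs$rna_seq))
  expect_true(cc94$closed)
  expect_equal(cc94$gauc_variant, "GAUG")
})

test_that("verify_motifs accepts designed hairpins and rejects unpaired intervals", {
  st <- fold_rna("GGGGAAAACCCCAAAAAAAA")
  ann <- data.frame(name = c("helix", "loop"),
                    start = c(1, 13), end = c(12, 20))
  out <- verify_motifs(st, ann)
  expect_true(out$verified[out$name == "helix"])
  expect_false(out$verified[out$name == "loop"])
  expect_error(verify_motifs(st, data.frame(name = c("a", "a"),
                                            start = c(1, 1),
                                            end = c(5, 5))),
               "duplicate")
  set.seed(62)
  cs <- make_cassette()
  mv <- verify_motifs(fold_rna(cs$rna_seq), cs$motifs)
  expect_equal(sum(mv$verified), 5)
})

test_that("dot-bracket output parses back to the same structure", {
  set.seed(205)
  s <- random_dna(40, gc = 0.5)
  st <- fold_rna(s)
  f <- tempfile(fileext = ".db")
  write_dotbracket(st, f, id = "x")
  st2 <- read_dotbracket(f)
  expect_equal(st2$sequence, st$sequence)
  expect_equal(st2$pairs, st$pairs, ignore_attr = TRUE)
  expect_equal(st2$energy, st$energy, tolerance = 0.01)
  expect_error(parse_dotbracket("(()"), "unbalanced")
})
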