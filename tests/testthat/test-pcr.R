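test_that("find_amplicon obeys orientation and reports exact products", {
  set.seed(301)
  tmpl <- random_dna(300, 0.5)
  fwd <- substr(tmpl, 21, 40)
  rev <- rc_chr(substr(tmpl, 211, 230))
  amp <- find_amplicon(tmpl, fwd, rev)
  expect_equal(amp$start, 21)
  expect_equal(amp$end, 230)
  expect_equal(amp$length, 210)

  # reverse site upstream of the forward site: no product
  expect_null(find_amplicon(tmpl, substr(tmpl, 211, 230),
                            rc_chr(substr(tmpl, 21, 40))))

  # full-length amplicon from terminal primers
  expect_equal(find_amplicon(tmpl, substr(tmpl, 1, 12),
                             rc_chr(substr(tmpl, 289, 300)))$length, 300)
  expect_error(find_amplicon(tmpl, "ACGTACG", rev), "shorter than 10")
  expect_error(find_amplicon("", fwd, rev), "empty template")
})

test_that("find_amplicon matches the brute-force substring oracle", {
  set.seed(302)
  for (rep in 1:500) {
    tmpl <- random_dna(150, 0.5)
    fs <- sample(1:60, 1)
    re <- sample(90:150, 1)
    fwd <- substr(tmpl, fs, fs + 11)
    rev <- rc_chr(substr(tmpl, re - 11, re))
    amp <- find_amplicon(tmpl, fwd, rev)
    oracle <- brute_amplicon_length(tmpl, fwd, rev)
    if (is.null(oracle)) expect_null(amp)
    else expect_equal(amp$length, oracle)
  }
})

test_that("mismatch tolerance spares the 3'-terminal trinucleotide", {
  set.seed(303)
  tmpl <- random_dna(120, 0.5)
  fwd <- substr(tmpl, 11, 26)
  rev <- rc_chr(substr(tmpl, 91, 106))
  mutate_at <- function(p, i) {
    b <- substr(p, i, i)
    paste0(substr(p, 1, i - 1), setdiff(c("A", "C", "G", "T"), b)[1],
           substr(p, i + 1, nchar(p)))
  }
  # internal mismatch: tolerated at max_mismatch = 1
  f_mid <- mutate_at(fwd, 5)
  expect_null(find_amplicon(tmpl, f_mid, rev, max_mismatch = 0))
  expect_equal(find_amplicon(tmpl, f_mid, rev, max_mismatch = 1)$length,
               96)
  # 3'-terminal mismatch: rejected even with tolerance
  f_end <- mutate_at(fwd, 16)
  expect_null(find_amplicon(tmpl, f_end, rev, max_mismatch = 1))
})

test_that("the least saturated dilution follows the protocol rule", {
  sat <- 0.9
  s1 <- dilution_series("rp49", 6:8, c(1.0, 0.95, 0.4),
                        saturation_threshold = sat)
  expect_equal(least_saturated_dilution(s1), 8L)
  s2 <- dilution_series("rp49", 6:8, c(0.5, 0.3, 0.1),
                        saturation_threshold = sat)
  expect_equal(least_saturated_dilution(s2), 6L)
  s3 <- dilution_series("rp49", 6:8, c(0, 0, 0))
  expect_error(least_saturated_dilution(s3), "no usable dilution")
  expect_error(dilution_series("x", c(6, 6, 8), c(1, 1, 1)),
               "strictly increasing")
})

test_that("relative expression is an identity on self, scale-invariant, zero-capable", {
  ref <- dilution_series("rp49", 6:8, c(1.0, 0.95, 0.4))
  expect_equal(relative_expression(ref, ref)$target_over_reference, 1.0)

  tgt <- dilution_series("7SK94F", 6:8, c(0.9, 0.5, 0.1))
  r1 <- relative_expression(tgt, ref)
  scale <- function(s, k) dilution_series(s$sample_id, s$exponents,
                                          s$intensities * k,
                                          saturation_threshold =
                                            s$saturation_threshold * k)
  r2 <- relative_expression(scale(tgt, 3), scale(ref, 3))
  expect_equal(r1$target_over_reference, r2$target_over_reference)
  expect_equal(r1$chosen_exponent, 8L)

  zero <- dilution_series("off", 6:8, c(0, 0, 0))
  expect_equal(relative_expression(zero, ref)$target_over_reference, 0)

  short <- dilution_series("7SK94F", 6:7, c(0.9, 0.5))
  expect_error(relative_expression(short, ref), "no measurement")
})

test_that("cross-sample factors follow the 5-fold dilution arithmetic", {
  expect_equal(dilution_scale_factor(8, 6), 25)
  expect_equal(dilution_scale_factor(6, 8), 1 / 25)
  expect_equal(dilution_scale_factor(7, 7), 1)
})

test_that("band-intensity CSVs build dilution series per sample and gene", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample,gene,exponent,intensity",
               "embryo,rp49,6,1.0", "embryo,rp49,7,0.95",
               "embryo,rp49,8,0.4",
               "embryo,7SK94F,6,0.2", "embryo,7SK94F,7,0.1",
               "embryo,7SK94F,8,0.02"), f)
  x <- read_band_intensities(f)
  expect_named(x, "embryo")
  r <- relative_expression(x$embryo$`7SK94F`, x$embryo$rp49)
  expect_equal(r$chosen_exponent, 8L)
  expect_equal(r$target_over_reference, 0.02 / 0.4)
})
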