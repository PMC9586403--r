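# Synthetic-data generator: construct assembly, excision products,
# multinomial outcomes, paired-end FASTQ emission.

test_that("construct carries two copies of each lox site and the variant in both loxP copies", {
  variant <- "GATGTCAAGATAG"
  cons <- build_construct(variant, fixture_config)
  s <- cons$sequence
  # substring-scan oracle on the assembled amplicon
  expect_identical(count_occurrences(loxp_anchor(), s), 2L)
  expect_identical(count_occurrences(lox2272_anchor(), s), 2L)
  expect_identical(count_occurrences(paste0(loxp_anchor(), variant), s), 2L)
  expect_identical(count_occurrences(paste0(lox2272_anchor(), wt_rbe()), s), 2L)
  expect_identical(count_occurrences(fixture_config$markerA, s), 1L)
  expect_identical(count_occurrences(fixture_config$markerB, s), 1L)
  # element coordinates tile the amplicon
  el <- cons$elements
  expect_identical(el$start[1], 0L)
  expect_identical(el$end[nrow(el)], nchar(s))
  expect_identical(el$start[-1], el$end[-nrow(el)])
  for (i in seq_len(nrow(el))) {
    if (el$name[i] == "loxP_1" || el$name[i] == "loxP_2") {
      expect_identical(substr(s, el$start[i] + 1, el$end[i]),
                       paste0(loxp_anchor(), variant))
    }
  }
  # a 2x150 pair covers the whole uncleaved amplicon
  expect_lte(nchar(s), 280L)
})

test_that("construct configuration is deterministic per seed and anchor-free", {
  a <- construct_config(seed = 5)
  b <- construct_config(seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$markerA, construct_config(seed = 6)$markerA))
  for (el in c(a$markerA, a$markerB, a$flank5, a$flank3, a$stuffer)) {
    expect_identical(count_occurrences(loxp_anchor(), el), 0L)
    expect_identical(count_occurrences(lox2272_anchor(), el), 0L)
  }
  expect_false(a$markerA == a$markerB)
})

test_that("excision products realize the marker decision table", {
  cons <- build_construct("AAAACGAAGTTAT", fixture_config)
  pr <- excision_products(cons)
  A <- fixture_config$markerA
  B <- fixture_config$markerB
  expect_identical(oracle_classify_amplicon(pr$uncleaved, A, B), "uncleaved")
  expect_identical(oracle_classify_amplicon(pr$loxP_product, A, B),
                   "loxP_cleaved")
  expect_identical(oracle_classify_amplicon(pr$lox2272_product, A, B),
                   "lox2272_cleaved")
  # each product still carries the variant RBE behind an intact loxP anchor
  probe <- paste0(loxp_anchor(), "AAAACGAAGTTAT")
  expect_identical(count_occurrences(probe, pr$loxP_product), 1L)
  expect_identical(count_occurrences(probe, pr$lox2272_product), 1L)
  # excision removes exactly the inter-site segment: products are shorter
  expect_lt(nchar(pr$loxP_product), nchar(pr$uncleaved))
  expect_lt(nchar(pr$lox2272_product), nchar(pr$uncleaved))
  # hybrid sites: one loxP and one lox2272 anchor left after loxP excision
  expect_identical(count_occurrences(loxp_anchor(), pr$loxP_product), 1L)
  expect_identical(count_occurrences(lox2272_anchor(), pr$loxP_product), 1L)
})

test_that("outcome draws are multinomial with conserved totals", {
  tr <- truth_record(wt_rbe(), p_noncleavage = 0.035,
                     p_loxP_given_cleaved = 0.3, n_molecules = 1e5)
  counts <- simulate_outcomes(tr, seed = 1)
  expect_identical(sum(counts), 100000L)
  # binomial moments: loxP count within 3 sigma of (1-p_nc)*p_loxP*n
  p <- (1 - 0.035) * 0.3
  expect_lt(abs(counts["loxP_cleaved"] - p * 1e5),
            3 * sqrt(p * (1 - p) * 1e5))
  # degenerate corners
  all_nc <- simulate_outcomes(truth_record(wt_rbe(), 1, 0.5, 1000), seed = 1)
  expect_identical(unname(all_nc["uncleaved"]), 1000L)
  no_loxP <- simulate_outcomes(truth_record(wt_rbe(), 0.1, 0, 1000), seed = 1)
  expect_identical(unname(no_loxP["loxP_cleaved"]), 0L)
  expect_identical(simulate_outcomes(tr, seed = 9),
                   simulate_outcomes(tr, seed = 9))
})

test_that("truth records validate their probabilities", {
  expect_error(truth_record(wt_rbe(), 1.2, 0.5, 10))
  expect_error(truth_record(wt_rbe(), 0.5, -0.1, 10))
  expect_error(truth_record(wt_rbe(), 0.5, 0.5, 0))
  expect_error(truth_record("NOTDNA", 0.5, 0.5, 10))
})

test_that("default truth model halves at WT and decays with substitutions", {
  tab <- reference_variants()
  tr <- default_truth(c(wt_rbe(), tab$sequence[1:5]))
  expect_equal(tr$p_loxP_given_cleaved[1], 0.5)
  k <- count_substitutions(tr$variant)
  expect_equal(tr$p_loxP_given_cleaved, 0.5 * 0.85^k)
  t1 <- table1_truth()
  expect_equal(t1$p_loxP_given_cleaved, tab$cleavage_rate_pct / 100)
})

test_that("read pairs cover the amplicon ends and zero-error mates are verbatim", {
  tr <- truth_record(wt_rbe(), p_noncleavage = 1, p_loxP_given_cleaved = 0.5,
                     n_molecules = 3)
  pairs <- simulate_read_pairs(tr, config = fixture_config, error_rate = 0,
                               seed = 1)
  cons <- build_construct(wt_rbe(), fixture_config)
  amp <- cons$sequence
  expect_identical(unique(pairs$m1), substr(amp, 1, 150))
  m2_expected <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(amp, nchar(amp) - 149, nchar(amp)))))
  expect_identical(unique(pairs$m2), m2_expected)
  expect_true(grepl(paste0(loxp_anchor(), wt_rbe()), pairs$m1[1], fixed = TRUE))
})

test_that("FASTQ output is byte-identical across reruns and parses back", {
  tr <- default_truth(c(wt_rbe(), "AAAACGAAGTTAT"), n_molecules = 50)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  out1 <- generate_fastq(tr, d1, config = fixture_config, seed = 11)
  out2 <- generate_fastq(tr, d2, config = fixture_config, seed = 11)
  expect_identical(readLines(out1$r1), readLines(out2$r1))
  expect_identical(readLines(out1$r2), readLines(out2$r2))
  r1 <- Biostrings::readDNAStringSet(out1$r1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(out1$r2, format = "fastq")
  expect_length(r1, 100)
  expect_identical(names(r1), names(r2))
  # markers config round-trips and drives classification downstream
  mk <- read_markers(out1$markers)
  expect_identical(mk$markerA, fixture_config$markerA)
  truth_back <- read.delim(out1$truth)
  expect_identical(truth_back$variant, tr$variant)
})

test_that("substitution errors degrade exact-match extraction monotonically", {
  tr <- default_truth(wt_rbe(), n_molecules = 400)
  fail_frac <- vapply(c(0, 0.01, 0.05), function(er) {
    pairs <- simulate_read_pairs(tr, config = fixture_config,
                                 error_rate = er, seed = 21)
    v <- extract_variant(pairs$m1, pairs$m2)
    mean(is.na(v))
  }, numeric(1))
  expect_identical(fail_frac[1], 0)
  expect_lt(fail_frac[2], fail_frac[3])
  expect_error(simulate_read_pairs(tr, error_rate = 0.5), "\\[0, 0.2\\]")
})
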