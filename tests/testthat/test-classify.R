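# Read-pair classification: anchor-based RBE extraction, marker decision
# table, per-variant tallies, rate algebra, and the estimate table.

pad <- function(...) paste0(...)

test_that("variant extraction follows the anchor on either mate and strand", {
  v <- "GATGTCAAGATAG"
  fwd <- pad("ACGT", loxp_anchor(), v, "TTTTGGGG")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  blank <- strrep("A", 60)
  expect_identical(extract_variant(fwd, blank), v)
  expect_identical(extract_variant(blank, fwd), v)
  expect_identical(extract_variant(rc, blank), v)
  expect_identical(extract_variant(blank, rc), v)
  # no anchor anywhere -> failure, distinct from classification
  expect_identical(extract_variant(blank, blank), NA_character_)
  # anchor flush against the read end: no room for the 13-mer
  truncated <- pad("ACGT", loxp_anchor(), substr(v, 1, 6))
  expect_identical(extract_variant(truncated, blank), NA_character_)
  # concordant duplicate occurrences agree -> single call
  double <- pad(loxp_anchor(), v, "CCCC", loxp_anchor(), v)
  expect_identical(extract_variant(double, blank), v)
  # discordant occurrences within one pair -> failure, not a vote
  discordant <- pad(loxp_anchor(), v, "CCCC", loxp_anchor(), wt_rbe())
  expect_identical(extract_variant(discordant, blank), NA_character_)
  # the lox2272 anchor must not trigger loxP extraction
  lox2272_only <- pad("ACGT", lox2272_anchor(), wt_rbe())
  expect_identical(extract_variant(lox2272_only, blank), NA_character_)
  # vectorized over pairs
  expect_identical(extract_variant(c(fwd, blank), c(blank, blank)),
                   c(v, NA_character_))
})

test_that("marker decision table classifies all four outcomes", {
  mk <- fixture_config
  A <- mk$markerA
  B <- mk$markerB
  blank <- strrep("T", 40)
  both <- pad("AC", A, "GT", B)
  onlyA <- pad("AC", A, "GT")
  onlyB_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pad("AC", B, "GT"))))
  cases <- classify_pair(c(both, onlyA, blank, blank),
                         c(blank, blank, onlyB_rc, blank), mk)
  expect_identical(as.character(cases),
                   c("uncleaved", "loxP_cleaved", "lox2272_cleaved",
                     "unclassified"))
  # markers split across the two mates still mean uncleaved
  split <- classify_pair(onlyA, pad(B, "AAAA"), mk)
  expect_identical(as.character(split), "uncleaved")
  bad <- fixture_config
  bad$markerB <- bad$markerA
  expect_error(classify_pair("ACGT", "ACGT", bad), "must differ")
})

test_that("rate algebra matches the printed formulas", {
  expect_equal(cleavage_rate(173, 827), 17.3)
  expect_equal(cleavage_rate(0, 500), 0)
  expect_equal(round(cleavage_rate(425, 277), 1), 60.5)
  expect_true(is.na(cleavage_rate(0, 0)))
  expect_equal(non_cleavage_rate(35, 300, 665), 3.5)
  expect_equal(non_cleavage_rate(0, 10, 10), 0)
  expect_true(is.na(non_cleavage_rate(0, 0, 0)))
  # vectorized
  expect_equal(cleavage_rate(c(1, 0), c(1, 0)), c(50, NA))
})

test_that("tallies conserve counts and route failures to the global counter", {
  empty <- tally_pairs(character(0), character(0), fixture_config)
  expect_identical(nrow(empty$counts), 0L)
  expect_identical(empty$n_extraction_failures, 0L)

  v <- "AAAACGAAGTTAT"
  A <- fixture_config$markerA
  with_var_no_marker <- pad(loxp_anchor(), v, "GGGG")
  with_var_A <- pad(loxp_anchor(), v, "GG", A)
  no_var <- strrep("C", 50)
  tl <- tally_pairs(c(with_var_no_marker, with_var_A, no_var),
                    rep(strrep("T", 30), 3), fixture_config)
  expect_identical(tl$n_extraction_failures, 1L)
  row <- tl$counts[tl$counts$variant == v, ]
  expect_identical(row$n_unclassified, 1L)
  expect_identical(row$n_loxP_cleaved, 1L)
  expect_identical(row$n_reads, 1L)  # classified = total - unclassified
})

test_that("zero-noise tallies equal the simulated outcomes exactly", {
  tr <- spread_truth(8, n_molecules = 300, seed = 4)
  pairs <- simulate_read_pairs(tr, config = fixture_config, error_rate = 0,
                               seed = 4)
  tl <- tally_pairs(pairs$m1, pairs$m2, fixture_config)
  expect_identical(tl$n_extraction_failures, 0L)
  truth_counts <- table(pairs$variant, pairs$outcome)
  for (i in seq_len(nrow(tl$counts))) {
    v <- tl$counts$variant[i]
    expect_identical(tl$counts$n_uncleaved[i],
                     unname(truth_counts[v, "uncleaved"]))
    expect_identical(tl$counts$n_loxP_cleaved[i],
                     unname(truth_counts[v, "loxP_cleaved"]))
    expect_identical(tl$counts$n_lox2272_cleaved[i],
                     unname(truth_counts[v, "lox2272_cleaved"]))
  }
  # global conservation: attributed + failures = all pairs
  expect_identical(sum(tl$counts$n_reads + tl$counts$n_unclassified) +
                     tl$n_extraction_failures,
                   nrow(pairs))
})

test_that("estimate_library applies the strict cutoff and Table-1 ordering", {
  tr <- spread_truth(6, n_molecules = 400, seed = 5)
  pairs <- simulate_read_pairs(tr, config = fixture_config, seed = 5)
  est <- estimate_library(pairs$m1, pairs$m2, fixture_config, cutoff = 500)
  expect_identical(nrow(est), 6L)
  # depth 400 < cutoff: nothing passes, rows still reported
  expect_false(any(est$passes_cutoff))
  # boundary: exactly `cutoff` classified reads must fail a strict cutoff
  expect_false(any(est$n_reads[est$n_reads == 500] > 500))
  expect_true(all(diff(est$cleavage_rate_pct) >= 0))
  expect_identical(est$n_substitutions, count_substitutions(est$variant))

  est2 <- estimate_library(pairs$m1, pairs$m2, fixture_config, cutoff = 300)
  expect_true(all(est2$passes_cutoff))

  # single-variant input -> one row
  one <- simulate_read_pairs(default_truth(wt_rbe(), n_molecules = 50),
                             config = fixture_config, seed = 6)
  est1 <- estimate_library(one$m1, one$m2, fixture_config)
  expect_identical(nrow(est1), 1L)

  expect_error(estimate_library(strrep("A", 50), strrep("A", 50),
                                fixture_config),
               "no classifiable")
})

test_that("estimate_library reads paired FASTQ files and round-trips TSV", {
  tr <- spread_truth(4, n_molecules = 200, seed = 6)
  d <- withr::local_tempdir()
  out <- generate_fastq(tr, d, config = fixture_config, seed = 6)
  est_files <- estimate_library(out$r1, out$r2, out$markers, cutoff = 100)
  est_mem <- estimate_library(out$pairs$m1, out$pairs$m2, fixture_config,
                              cutoff = 100)
  expect_equal(est_files, est_mem, ignore_attr = TRUE)
  tsv <- file.path(d, "estimates.tsv")
  write_estimates(est_files, tsv)
  back <- read.delim(tsv)
  expect_identical(back$variant, est_files$variant)
  expect_equal(back$cleavage_rate_pct, round(est_files$cleavage_rate_pct, 1))
  expect_error(estimate_library(out$r1, c("ACGT", "ACGT"), fixture_config),
               "different numbers")
})

test_that("recovered rates track truth at moderate depth", {
  tr <- spread_truth(30, n_molecules = 1500, seed = 7)
  pairs <- simulate_read_pairs(tr, config = fixture_config, seed = 7)
  est <- estimate_library(pairs$m1, pairs$m2, fixture_config, cutoff = 500)
  m <- merge(est, tr, by = "variant")
  expect_identical(nrow(m), 30L)
  r2 <- cor(m$cleavage_rate_pct, 100 * m$p_loxP_given_cleaved)^2
  expect_gt(r2, 0.99)
  nc <- mean(m$non_cleavage_rate_pct)
  expect_lt(abs(nc - 3.5), 1)
})
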