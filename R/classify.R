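# Read classification: extract each pair's variant RBE by exact anchor
# matching, classify the recombination outcome from the diagnostic markers,
# tally per variant, and compute cleavage / non-cleavage rates.
#
# Matching is exact (0 mismatches) on both mates and their reverse
# complements; pairs whose anchor copies disagree on the extracted 13-mer are
# counted as extraction failures, not voted.

# Collect (pair index, extracted 13-mer) for every anchor hit across the four
# oriented sequence streams.
extract_all_kmers <- function(m1, m2, anchor, k = RBE_LEN) {
  streams <- list(m1, revcomp(m1), m2, revcomp(m2))
  alen <- nchar(anchor)
  hits <- lapply(streams, function(s) {
    dna <- Biostrings::DNAStringSet(s)
    m <- Biostrings::vmatchPattern(anchor, dna)
    counts <- S4Vectors::elementNROWS(m)
    idx <- rep(seq_along(s), counts)
    starts <- unlist(Biostrings::startIndex(m)[counts > 0], use.names = FALSE)
    if (length(idx) == 0) {
      return(data.table::data.table(idx = integer(0), kmer = character(0)))
    }
    from <- starts + alen
    to <- from + k - 1L
    ok <- to <= nchar(s)[idx]  # anchor too close to the read end: no 13-mer
    data.table::data.table(idx = idx[ok],
                           kmer = substr(s[idx[ok]], from[ok], to[ok]))
  })
  data.table::rbindlist(hits)
}

#' Extract the variant RBE from read pairs
#'
#' Scans both mates and their reverse complements for an exact occurrence of
#' the 21-base loxP anchor (left RBE + loxP spacer) and returns the 13 bases
#' immediately following it. A pair yields a variant only if every anchor
#' occurrence across the pair agrees on the same 13-mer; no occurrence, a
#' truncated occurrence at a read end, or discordant occurrences give `NA`
#' (an extraction failure, counted separately from classification).
#'
#' @param m1,m2 Character vectors of mate-1 / mate-2 sequences (same length).
#' @param anchor The loxP anchor; defaults to [loxp_anchor()].
#' @return Character vector of 13-mers, `NA` where extraction failed.
#' @export
extract_variant <- function(m1, m2, anchor = loxp_anchor()) {
  stopifnot(length(m1) == length(m2))
  n <- length(m1)
  if (n == 0) return(character(0))
  km <- extract_all_kmers(m1, m2, anchor)
  out <- rep(NA_character_, n)
  if (nrow(km) > 0) {
    agreed <- km[, .(kmer = if (data.table::uniqueN(kmer) == 1L) kmer[1L]
                     else NA_character_),
                 by = idx]
    out[agreed$idx] <- agreed$kmer
  }
  out
}

# Marker present in either mate, either strand (exact match).
marker_present <- function(m1, m2, marker) {
  dna1 <- Biostrings::DNAStringSet(m1)
  dna2 <- Biostrings::DNAStringSet(m2)
  rc <- revcomp(marker)
  (Biostrings::vcountPattern(marker, dna1) +
     Biostrings::vcountPattern(rc, dna1) +
     Biostrings::vcountPattern(marker, dna2) +
     Biostrings::vcountPattern(rc, dna2)) > 0
}

OUTCOME_LEVELS <- c("uncleaved", "loxP_cleaved", "lox2272_cleaved",
                    "unclassified")

#' Classify read pairs into recombination outcomes
#'
#' Decision table on exact marker presence across the pair (both mates, both
#' strands): markerA and markerB present = uncleaved; markerA only = cleaved
#' between loxP; markerB only = cleaved between lox2272; neither =
#' unclassified. Every pair lands in exactly one of the four classes.
#'
#' @param m1,m2 Character vectors of mate sequences.
#' @param markers A [construct_config()] (or list with `markerA`, `markerB`).
#' @return Factor with levels uncleaved / loxP_cleaved / lox2272_cleaved /
#'   unclassified.
#' @export
classify_pair <- function(m1, m2, markers) {
  stopifnot(length(m1) == length(m2))
  if (markers$markerA == markers$markerB) {
    stop("markerA and markerB must differ", call. = FALSE)
  }
  if (length(m1) == 0) return(factor(character(0), levels = OUTCOME_LEVELS))
  hasA <- marker_present(m1, m2, markers$markerA)
  hasB <- marker_present(m1, m2, markers$markerB)
  out <- ifelse(hasA & hasB, "uncleaved",
         ifelse(hasA, "loxP_cleaved",
         ifelse(hasB, "lox2272_cleaved", "unclassified")))
  factor(out, levels = OUTCOME_LEVELS)
}

#' Tally classified pairs per variant
#'
#' Attributes each pair to exactly one (variant, outcome) cell, or — when the
#' variant RBE could not be extracted — to a global extraction-failure
#' counter.
#'
#' @param m1,m2 Character vectors of mate sequences.
#' @param markers A [construct_config()].
#' @return A list with `counts` (data.table: `variant`, `n_uncleaved`,
#'   `n_loxP_cleaved`, `n_lox2272_cleaved`, `n_unclassified`, `n_reads`) and
#'   `n_extraction_failures`. `n_reads` is the number of pairs in the three
#'   recombination classes (total minus unclassified).
#' @export
tally_pairs <- function(m1, m2, markers) {
  variant <- extract_variant(m1, m2, markers$anchor_loxP %||% loxp_anchor())
  outcome <- classify_pair(m1, m2, markers)
  keep <- !is.na(variant)
  dt <- data.table::data.table(variant = variant[keep],
                               outcome = outcome[keep])
  counts <- data.table::dcast(
    dt[, .N, by = .(variant, outcome)],
    variant ~ outcome, value.var = "N", fill = 0L, drop = c(TRUE, FALSE))
  for (lev in OUTCOME_LEVELS) {
    if (!lev %in% names(counts)) counts[, (lev) := 0L]
  }
  data.table::setnames(counts, OUTCOME_LEVELS,
                       c("n_uncleaved", "n_loxP_cleaved", "n_lox2272_cleaved",
                         "n_unclassified"))
  counts[, n_reads := n_uncleaved + n_loxP_cleaved + n_lox2272_cleaved]
  list(counts = counts[], n_extraction_failures = sum(!keep))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cleavage rate between loxP sites
#'
#' The per-variant statistic of the screen:
#' 100 * n_loxP / (n_loxP + n_lox2272). Uncleaved and unclassified pairs are
#' excluded from the denominator — the rate measures the outcome of the
#' competition between the two recombinable site pairs among molecules that
#' recombined.
#'
#' @param n_loxP,n_lox2272 Read-pair counts (vectors allowed).
#' @return Percentage in \[0, 100\]; `NA` where the denominator is zero.
#' @export
cleavage_rate <- function(n_loxP, n_lox2272) {
  denom <- n_loxP + n_lox2272
  ifelse(denom > 0, 100 * n_loxP / denom, NA_real_)
}

#' Non-cleavage rate
#'
#' 100 * n_uncleaved / (n_uncleaved + n_loxP + n_lox2272); unclassified pairs
#' are excluded from the denominator.
#'
#' @param n_uncleaved,n_loxP,n_lox2272 Read-pair counts (vectors allowed).
#' @return Percentage in \[0, 100\]; `NA` where the denominator is zero.
#' @export
non_cleavage_rate <- function(n_uncleaved, n_loxP, n_lox2272) {
  denom <- n_uncleaved + n_loxP + n_lox2272
  ifelse(denom > 0, 100 * n_uncleaved / denom, NA_real_)
}

#' Estimate per-variant cleavage rates from paired FASTQ (or in-memory pairs)
#'
#' The full Illumina-analysis path: parse the read pairs, extract each pair's
#' variant RBE, classify its recombination outcome, tally per variant, apply
#' the read-depth cutoff (strictly more than `cutoff` classified pairs), and
#' compute cleavage and non-cleavage rates. Rows are sorted by ascending
#' cleavage rate, i.e. strongest loss of Cre recognition first.
#'
#' @param r1,r2 Paths to the mate FASTQ files (plain or gzip), or character
#'   vectors of sequences.
#' @param markers A [construct_config()] or path to a `markers.yaml`.
#' @param cutoff Read-depth cutoff; a variant passes with `n_reads > cutoff`.
#' @return A `data.frame` with columns `variant`, `n_substitutions`,
#'   `n_uncleaved`, `n_loxP`, `n_lox2272`, `n_unclassified`, `n_reads`,
#'   `cleavage_rate_pct`, `non_cleavage_rate_pct`, `passes_cutoff`; attribute
#'   `n_extraction_failures` carries the global failure count.
#' @export
estimate_library <- function(r1, r2, markers, cutoff = 500L) {
  read_seqs <- function(x, which) {
    if (length(x) == 1 && file.exists(x)) {
      rec <- tryCatch(
        Biostrings::readDNAStringSet(x, format = "fastq"),
        error = function(e) stop(sprintf("unreadable FASTQ %s: %s", x,
                                         conditionMessage(e)), call. = FALSE))
      as.character(rec)
    } else {
      x
    }
  }
  if (is.character(markers) && length(markers) == 1 && file.exists(markers)) {
    markers <- read_markers(markers)
  }
  m1 <- read_seqs(r1, "R1")
  m2 <- read_seqs(r2, "R2")
  if (length(m1) != length(m2)) {
    stop("mate files contain different numbers of reads", call. = FALSE)
  }
  tl <- tally_pairs(m1, m2, markers)
  counts <- tl$counts
  if (nrow(counts) == 0) {
    stop(sprintf(
      "no classifiable read pairs (%d pairs, %d extraction failures)",
      length(m1), tl$n_extraction_failures), call. = FALSE)
  }
  est <- data.frame(
    variant = counts$variant,
    n_substitutions = count_substitutions(counts$variant),
    n_uncleaved = counts$n_uncleaved,
    n_loxP = counts$n_loxP_cleaved,
    n_lox2272 = counts$n_lox2272_cleaved,
    n_unclassified = counts$n_unclassified,
    n_reads = counts$n_reads,
    cleavage_rate_pct = cleavage_rate(counts$n_loxP_cleaved,
                                      counts$n_lox2272_cleaved),
    non_cleavage_rate_pct = non_cleavage_rate(counts$n_uncleaved,
                                              counts$n_loxP_cleaved,
                                              counts$n_lox2272_cleaved),
    passes_cutoff = counts$n_reads > cutoff,
    stringsAsFactors = FALSE
  )
  est <- est[order(est$cleavage_rate_pct, est$variant, na.last = TRUE), ]
  rownames(est) <- NULL
  attr(est, "n_extraction_failures") <- tl$n_extraction_failures
  est
}

#' Write a per-variant estimate table as TSV
#'
#' Rates are rounded to 1 decimal in the file; the in-memory table keeps full
#' precision.
#'
#' @param estimates Output of [estimate_library()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  out <- estimates
  out$cleavage_rate_pct <- round1(out$cleavage_rate_pct)
  out$non_cleavage_rate_pct <- round1(out$non_cleavage_rate_pct)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
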