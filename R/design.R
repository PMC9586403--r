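# Library design: the biased-randomization (doped-oligo) model of the 13-bp
# right RBE, its binomial substitution-count distribution, variant-space
# enumeration, coverage and per-position composition.

#' Substitution-count distribution of a doped-oligo design
#'
#' In biased randomization each of the `length` positions keeps the original
#' base with probability `retention_pct`/100 and otherwise becomes one of the
#' three alternatives (each (100 - retention_pct)/300). The number of
#' substituted bases y is therefore binomial:
#'
#'   P(y) = C(L, y) * (x/100)^(L - y) * ((100 - x)/100)^y
#'
#' with x the retention percentage and L the randomized length. At the
#' screen's design value x = 84.7 the mode is y = 2, i.e. the doping rate is
#' tuned to maximize double substitutions (about 29.4% of the library).
#'
#' @param retention_pct Per-base retention percentage x in \[0, 100\].
#' @param length Number of randomized positions (13 for the right RBE).
#' @return Numeric vector of probabilities named `"0"` ... `"length"`,
#'   summing to 1.
#' @examples
#' p <- substitution_count_distribution(84.7)
#' which.max(p) - 1  # modal substitution count: 2
#' @export
substitution_count_distribution <- function(retention_pct, length = RBE_LEN) {
  if (!is.numeric(retention_pct) || length(retention_pct) != 1 ||
      is.na(retention_pct) || retention_pct < 0 || retention_pct > 100) {
    stop("`retention_pct` must be a single value in [0, 100]", call. = FALSE)
  }
  p_mut <- (100 - retention_pct) / 100
  y <- 0:length
  stats::setNames(stats::dbinom(y, size = length, prob = p_mut), y)
}

#' Doped-oligo design parameters
#'
#' Bundles the retention percentage with its implied per-alternative
#' percentage ((100 - x)/3 for each of the three non-original bases).
#'
#' @inheritParams substitution_count_distribution
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(retention_pct = 84.7, length = RBE_LEN) {
  # reuse the range validation
  substitution_count_distribution(retention_pct, length = 1)
  structure(
    list(retention_pct = retention_pct,
         length = as.integer(length),
         per_alternative_pct = (100 - retention_pct) / 3),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "Doped-oligo design: %d positions, %.1f%% retention, %.2f%% per alternative base\n",
    x$length, x$retention_pct, x$per_alternative_pct))
  invisible(x)
}

#' Count substitutions of RBE variants relative to wild type
#'
#' Hamming distance between each 13-mer and the wild-type right RBE
#' (`TATACGAAGTTAT`, top strand).
#'
#' @param sequence Character vector of 13-base sequences over A/C/G/T.
#' @param wt Reference sequence (defaults to the wild-type right RBE).
#' @return Integer vector of substitution counts.
#' @examples
#' count_substitutions(c("TATACGAAGTTAT", "AAAACGAAGTTAT"))
#' @export
count_substitutions <- function(sequence, wt = wt_rbe()) {
  sequence <- validate_rbe(sequence, len = nchar(wt))
  wt_chars <- strsplit(wt, "")[[1]]
  vapply(strsplit(sequence, ""), function(s) sum(s != wt_chars), integer(1))
}

#' Mutated positions of RBE variants
#'
#' 1-based positions at which each sequence differs from the wild type.
#'
#' @inheritParams count_substitutions
#' @return A list of integer vectors, one per sequence.
#' @export
substituted_positions <- function(sequence, wt = wt_rbe()) {
  sequence <- validate_rbe(sequence, len = nchar(wt))
  wt_chars <- strsplit(wt, "")[[1]]
  lapply(strsplit(sequence, ""), function(s) which(s != wt_chars))
}

#' Size (and optionally members) of a Hamming-distance variant class
#'
#' The class of 13-mers at Hamming distance exactly `k` from the wild-type
#' right RBE has C(13, k) * 3^k members (choose the positions, then one of 3
#' alternative bases at each). Explicit enumeration is only materialized for
#' small `k` (default bound 2) to keep memory bounded; larger classes are
#' counted analytically.
#'
#' @param k Substitution count, 0..13.
#' @param explicit If `TRUE`, return the class members as a character vector.
#' @param max_explicit_k Largest `k` for which explicit enumeration is
#'   permitted.
#' @param wt Reference sequence.
#' @return The class size (numeric), or the member sequences if
#'   `explicit = TRUE`.
#' @examples
#' enumerate_variant_class(1)  # 39
#' enumerate_variant_class(2)  # 702
#' @export
enumerate_variant_class <- function(k, explicit = FALSE, max_explicit_k = 2L,
                                    wt = wt_rbe()) {
  len <- nchar(wt)
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k != round(k) ||
      k < 0 || k > len) {
    stop(sprintf("`k` must be an integer in 0..%d", len), call. = FALSE)
  }
  k <- as.integer(k)
  n <- choose(len, k) * 3^k
  if (!explicit) {
    return(n)
  }
  if (k > max_explicit_k) {
    stop(sprintf(
      "explicit enumeration capped at k <= %d (class size %s); raise `max_explicit_k` to override",
      max_explicit_k, format(n, big.mark = ",")), call. = FALSE)
  }
  wt_chars <- strsplit(wt, "")[[1]]
  if (k == 0L) {
    return(wt)
  }
  pos_sets <- utils::combn(len, k, simplify = FALSE)
  out <- character(n)
  i <- 0L
  for (pos in pos_sets) {
    alts <- lapply(pos, function(p) setdiff(BASES, wt_chars[p]))
    combos <- as.matrix(expand.grid(alts, stringsAsFactors = FALSE))
    for (r in seq_len(nrow(combos))) {
      s <- wt_chars
      s[pos] <- combos[r, ]
      i <- i + 1L
      out[i] <- paste(s, collapse = "")
    }
  }
  out
}

#' Draw a biased-randomization library
#'
#' Simulates doped-oligo synthesis: each position of each draw independently
#' keeps the wild-type base with probability `retention_pct`/100, otherwise
#' becomes one of the three alternatives uniformly.
#'
#' @param spec A [design_spec()] (or a bare retention percentage).
#' @param n_variants Number of molecules to draw.
#' @param seed Integer seed; draws are reproducible for a fixed seed.
#' @return A `data.frame` with columns `sequence`, `n_substitutions`, and
#'   `positions` (comma-separated 1-based mutated positions).
#' @export
sample_library <- function(spec = design_spec(), n_variants, seed = NULL) {
  if (is.numeric(spec)) spec <- design_spec(spec)
  stopifnot(inherits(spec, "design_spec"))
  if (!is.numeric(n_variants) || n_variants < 1) {
    stop("`n_variants` must be >= 1", call. = FALSE)
  }
  n <- as.integer(n_variants)
  len <- spec$length
  keep_p <- spec$retention_pct / 100
  wt_chars <- strsplit(wt_rbe(), "")[[1]][seq_len(len)]
  with_seed(seed, {
    mat <- matrix(rep(wt_chars, each = n), nrow = n)
    for (j in seq_len(len)) {
      hit <- stats::runif(n) >= keep_p
      if (any(hit)) {
        alts <- setdiff(BASES, wt_chars[j])
        mat[hit, j] <- sample(alts, sum(hit), replace = TRUE)
      }
    }
    seqs <- apply(mat, 1, paste, collapse = "")
    nsub <- count_substitutions(seqs)
    pos <- vapply(substituted_positions(seqs),
                  function(p) paste(p, collapse = ","), character(1))
    data.frame(sequence = seqs, n_substitutions = nsub, positions = pos,
               stringsAsFactors = FALSE)
  })
}

#' Coverage rate of a substitution class
#'
#' Percentage of the C(13, k) * 3^k possible k-substitution variants that are
#' present (as distinct sequences) in an observed set.
#'
#' @param observed Character vector of observed variant sequences, or a
#'   data.frame with a `sequence` column (e.g. from [sample_library()]).
#' @param k Substitution class.
#' @param wt Reference sequence.
#' @return Coverage percentage in \[0, 100\].
#' @export
coverage_rate <- function(observed, k, wt = wt_rbe()) {
  if (is.data.frame(observed)) observed <- observed$sequence
  class_size <- enumerate_variant_class(k, wt = wt)
  if (length(observed) == 0) {
    return(0)
  }
  observed <- unique(validate_rbe(observed, len = nchar(wt)))
  n_obs <- sum(count_substitutions(observed, wt = wt) == k)
  100 * n_obs / class_size
}

#' Per-position base composition of a variant set
#'
#' Weighted base fractions at each of the 13 RBE positions, e.g. weighted by
#' read counts to reproduce the per-position nucleotide rates of a sequenced
#' library.
#'
#' @param variants Character vector of sequences, or a data.frame with a
#'   `sequence` column.
#' @param weights Non-negative weights (recycled scalar allowed); defaults to
#'   equal weights.
#' @return A 13 x 4 numeric matrix (rows: positions 1..13, columns
#'   A/C/G/T); each row sums to 1.
#' @export
position_composition <- function(variants, weights = NULL) {
  if (is.data.frame(variants)) variants <- variants$sequence
  seqs <- validate_rbe(variants)
  n <- length(seqs)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) == 1) weights <- rep(weights, n)
  if (length(weights) != n || any(weights < 0) || anyNA(weights)) {
    stop("`weights` must be non-negative and match the number of variants",
         call. = FALSE)
  }
  if (sum(weights) == 0) {
    stop("all weights are zero; composition undefined", call. = FALSE)
  }
  len <- nchar(seqs[1])
  mat <- matrix(0, nrow = len, ncol = 4, dimnames = list(seq_len(len), BASES))
  chars <- matrix(unlist(strsplit(seqs, "")), ncol = len, byrow = TRUE)
  for (b in BASES) {
    mat[, b] <- colSums((chars == b) * weights)
  }
  mat / sum(weights)
}

#' Write a variant library as TSV and FASTA
#'
#' The TSV carries one row per draw (`variant_sequence`, `n_substitutions`,
#' `positions`); the FASTA holds the full 34-bp mutant loxP site
#' (left RBE + spacer + variant right RBE) for each distinct variant.
#'
#' @param library A data.frame from [sample_library()].
#' @param tsv_path,fasta_path Output paths (`NULL` to skip either).
#' @return Invisibly, the library.
#' @export
write_library <- function(library, tsv_path = NULL, fasta_path = NULL) {
  stopifnot(is.data.frame(library), "sequence" %in% names(library))
  if (!is.null(tsv_path)) {
    out <- data.frame(variant_sequence = library$sequence,
                      n_substitutions = library$n_substitutions,
                      positions = library$positions)
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(fasta_path)) {
    uniq <- unique(library$sequence)
    sites <- Biostrings::DNAStringSet(paste0(left_rbe(), loxp_spacer(), uniq))
    names(sites) <- sprintf("loxP_variant_%s", uniq)
    Biostrings::writeXStringSet(sites, fasta_path)
  }
  invisible(library)
}
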