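# Shared fixtures, built in code at test time.

# One construct configuration reused across tests (deterministic per seed).
fixture_config <- construct_config(seed = 42)

# Brute-force outcome oracle: classify a molecule by scanning its *source
# amplicon* (not the reads) for the two diagnostic markers with plain
# substring search. Independent of the package's read-level classifier.
oracle_classify_amplicon <- function(amplicon, markerA, markerB) {
  hasA <- grepl(markerA, amplicon, fixed = TRUE)
  hasB <- grepl(markerB, amplicon, fixed = TRUE)
  ifelse(hasA & hasB, "uncleaved",
  ifelse(hasA, "loxP_cleaved",
  ifelse(hasB, "lox2272_cleaved", "unclassified")))
}

# Count exact occurrences of a pattern in a string (both given strand only).
count_occurrences <- function(pattern, x) {
  m <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

# A small truth set with rates spread over the dynamic range of the screen.
spread_truth <- function(n_variants, lo = 0.005, hi = 0.60,
                         n_molecules = 2000L, seed = 1L,
                         p_noncleavage = 0.035) {
  lib <- sample_library(design_spec(), max(20L, 5L * n_variants), seed = seed)
  vars <- unique(lib$sequence)[seq_len(n_variants)]
  tr <- default_truth(vars, p_noncleavage = p_noncleavage,
                      n_molecules = n_molecules)
  tr$p_loxP_given_cleaved <- seq(lo, hi, length.out = n_variants)
  tr
}
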