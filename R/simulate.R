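# Synthetic-data generator: the competitive Cre-lox construct per variant,
# multinomial recombination outcomes, and paired-end reads with ground truth.
#
# Cassette layout (top strand, 0-based half-open coordinates):
#   5'flank | loxP#1 | markerB | lox2272#1 | stuffer | loxP#2 | markerA | lox2272#2 | 3'flank
# Both loxP copies carry the identical variant right RBE, so the variant
# identity survives either excision. Excising between the two loxP sites
# removes markerB (leaving markerA only = "sequence A"); excising between
# the two lox2272 sites removes markerA (leaving markerB only = "sequence B");
# the uncleaved molecule carries both.

FLANK_LEN <- 12L
MARKER_LEN <- 24L
STUFFER_LEN <- 20L

lox_site <- function(spacer, right) paste0(left_rbe(), spacer, right)

#' Construct configuration: marker tags, flanks, anchors
#'
#' Draws the run-wide random elements of the cassette (marker tags, flanks,
#' stuffer) once per seed, rejecting any draw that contains a lox anchor
#' (left RBE + spacer, either strand) or that collides with another element.
#' The tags play the role of the diagnostic "sequence A" (survives only loxP
#' excision) and "sequence B" (survives only lox2272 excision).
#'
#' @param seed Integer seed; the configuration is deterministic per seed.
#' @param marker_len,flank_len,stuffer_len Element lengths in bases.
#' @return A list of class `construct_config` with elements `markerA`,
#'   `markerB`, `flank5`, `flank3`, `stuffer`, `anchor_loxP`,
#'   `anchor_lox2272`, `seed`.
#' @export
construct_config <- function(seed = 1L, marker_len = MARKER_LEN,
                             flank_len = FLANK_LEN,
                             stuffer_len = STUFFER_LEN) {
  anchors <- c(loxp_anchor(), lox2272_anchor())
  forbidden <- c(anchors, revcomp(anchors))
  draw_clean <- function(len, avoid) {
    for (i in seq_len(100)) {
      s <- random_dna(1, len)
      hits <- vapply(c(forbidden, avoid), function(p) grepl(p, s, fixed = TRUE),
                     logical(1))
      if (!any(hits)) return(s)
    }
    stop("could not draw a cassette element free of anchor/marker collisions",
         call. = FALSE)
  }
  with_seed(seed, {
    markerB <- draw_clean(marker_len, character(0))
    markerA <- draw_clean(marker_len, c(markerB, revcomp(markerB)))
    avoid_mk <- c(markerA, markerB, revcomp(c(markerA, markerB)))
    flank5 <- draw_clean(flank_len, avoid_mk)
    flank3 <- draw_clean(flank_len, avoid_mk)
    stuffer <- draw_clean(stuffer_len, avoid_mk)
    structure(
      list(markerA = markerA, markerB = markerB,
           flank5 = flank5, flank3 = flank3, stuffer = stuffer,
           anchor_loxP = loxp_anchor(), anchor_lox2272 = lox2272_anchor(),
           seed = as.integer(seed)),
      class = "construct_config"
    )
  })
}

#' Build the competitive excision construct for one RBE variant
#'
#' Assembles the uncleaved amplicon for a variant, with both loxP copies
#' carrying the identical variant right RBE and both lox2272 copies the
#' canonical lox2272 site.
#'
#' @param variant A 13-base right-RBE sequence.
#' @param config A [construct_config()]; alternatively pass `seed` to build
#'   one on the fly.
#' @param seed Seed used only if `config` is missing.
#' @return A list of class `lox_construct`: `sequence` (uncleaved amplicon),
#'   `elements` (data.frame of 0-based half-open element coordinates),
#'   `variant`, `config`.
#' @export
build_construct <- function(variant, config = NULL, seed = 1L) {
  variant <- validate_rbe(variant)
  stopifnot(length(variant) == 1)
  if (is.null(config)) config <- construct_config(seed)
  stopifnot(inherits(config, "construct_config"))
  loxP_site <- lox_site(loxp_spacer(), variant)
  lox2272_site <- lox_site(lox2272_spacer(), wt_rbe())
  parts <- c(flank5 = config$flank5,
             loxP_1 = loxP_site,
             markerB = config$markerB,
             lox2272_1 = lox2272_site,
             stuffer = config$stuffer,
             loxP_2 = loxP_site,
             markerA = config$markerA,
             lox2272_2 = lox2272_site,
             flank3 = config$flank3)
  ends <- cumsum(nchar(parts))
  elements <- data.frame(name = names(parts),
                         start = c(0L, utils::head(ends, -1)),
                         end = ends,
                         stringsAsFactors = FALSE)
  structure(
    list(sequence = paste(parts, collapse = ""), elements = elements,
         variant = variant, config = config),
    class = "lox_construct"
  )
}

#' @export
print.lox_construct <- function(x, ...) {
  cat(sprintf("Competitive lox construct, variant %s (%d substitutions), %d bp\n",
              x$variant, count_substitutions(x$variant), nchar(x$sequence)))
  invisible(x)
}

# 0-based coordinate of a site's spacer midpoint (4 bases into the 8-bp spacer)
spacer_midpoint <- function(construct, element) {
  el <- construct$elements
  el$start[el$name == element] + RBE_LEN + 4L
}

#' Excision product amplicons of a construct
#'
#' Cre excision between two compatible same-orientation lox sites removes the
#' intervening segment and leaves a single hybrid site; here the excision
#' joint is modelled at the spacer midpoints. Because both loxP copies carry
#' the identical variant, the hybrid loxP of the loxP product still carries
#' that variant.
#'
#' @param construct A [build_construct()] result.
#' @return A list of three character amplicons: `uncleaved`, `loxP_product`
#'   (markerA only), `lox2272_product` (markerB only).
#' @export
excision_products <- function(construct) {
  stopifnot(inherits(construct, "lox_construct"))
  s <- construct$sequence
  cut_between <- function(m1, m2) {
    paste0(substr(s, 1L, m1), substr(s, m2 + 1L, nchar(s)))
  }
  list(
    uncleaved = s,
    loxP_product = cut_between(spacer_midpoint(construct, "loxP_1"),
                               spacer_midpoint(construct, "loxP_2")),
    lox2272_product = cut_between(spacer_midpoint(construct, "lox2272_1"),
                                  spacer_midpoint(construct, "lox2272_2"))
  )
}

#' Per-variant ground-truth record
#'
#' @param variant 13-base right-RBE sequence.
#' @param p_noncleavage Probability a molecule remains uncleaved.
#' @param p_loxP_given_cleaved Probability that a cleaved molecule was excised
#'   between the loxP pair (rather than the lox2272 pair); this is the true
#'   per-variant cleavage rate on the probability scale.
#' @param n_molecules Number of molecules to simulate for the variant.
#' @return A one-row data.frame.
#' @export
truth_record <- function(variant, p_noncleavage, p_loxP_given_cleaved,
                         n_molecules) {
  variant <- validate_rbe(variant)
  stopifnot(p_noncleavage >= 0, p_noncleavage <= 1,
            p_loxP_given_cleaved >= 0, p_loxP_given_cleaved <= 1,
            n_molecules >= 1)
  data.frame(variant = variant,
             p_noncleavage = p_noncleavage,
             p_loxP_given_cleaved = p_loxP_given_cleaved,
             n_molecules = as.integer(n_molecules),
             stringsAsFactors = FALSE)
}

#' Default truth model for simulated libraries
#'
#' Assigns each variant a true loxP cleavage probability that is 0.5 for the
#' wild type (symmetric competition between the two recognized site pairs)
#' and decays geometrically with the substitution count:
#' p_loxP(k) = 0.5 * decay^k. The non-cleavage probability defaults to the
#' screen-wide average of 3.5%.
#'
#' @param variants Character vector of RBE sequences.
#' @param p_noncleavage Shared non-cleavage probability.
#' @param decay Multiplicative affinity loss per substitution.
#' @param n_molecules Simulated depth per variant.
#' @return A truth data.frame (one row per variant).
#' @export
default_truth <- function(variants, p_noncleavage = 0.035, decay = 0.85,
                          n_molecules = 2000L) {
  variants <- validate_rbe(variants)
  k <- count_substitutions(variants)
  data.frame(variant = variants,
             p_noncleavage = p_noncleavage,
             p_loxP_given_cleaved = 0.5 * decay^k,
             n_molecules = as.integer(n_molecules),
             stringsAsFactors = FALSE)
}

#' Reference truth set from the published worst-50 variant table
#'
#' Loads the packaged table of the 50 mutant loxP sequences with the lowest
#' Cre recognition rates (right-RBE sequence, substitution count, measured
#' cleavage rate between loxP) and converts it to a truth table whose
#' p_loxP_given_cleaved equals the printed cleavage rate.
#'
#' @param p_noncleavage Shared non-cleavage probability.
#' @param n_molecules Simulated depth per variant.
#' @return A truth data.frame with an extra `reported_rate_pct` column.
#' @export
table1_truth <- function(p_noncleavage = 0.035, n_molecules = 2000L) {
  tab <- reference_variants()
  data.frame(variant = tab$sequence,
             p_noncleavage = p_noncleavage,
             p_loxP_given_cleaved = tab$cleavage_rate_pct / 100,
             n_molecules = as.integer(n_molecules),
             reported_rate_pct = tab$cleavage_rate_pct,
             stringsAsFactors = FALSE)
}

#' Published reference variant table
#'
#' The 50 lowest-cleavage-rate variants (sequence, substitution count,
#' cleavage rate between loxP in percent) shipped as a plain-text fixture.
#'
#' @return A data.frame with columns `sequence`, `n_substitutions`,
#'   `cleavage_rate_pct`.
#' @export
reference_variants <- function() {
  path <- system.file("extdata", "table1_variants.tsv", package = "loxscreen",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Draw molecule-level recombination outcomes for one variant
#'
#' Outcomes are multinomial over (uncleaved, loxP-excised, lox2272-excised)
#' with probabilities (p_nc, (1 - p_nc) p_loxP, (1 - p_nc)(1 - p_loxP)).
#'
#' @param truth A one-row truth data.frame (see [truth_record()]).
#' @param seed Integer seed.
#' @return Named integer vector `c(uncleaved, loxP_cleaved, lox2272_cleaved)`
#'   summing to `n_molecules`.
#' @export
simulate_outcomes <- function(truth, seed = NULL) {
  stopifnot(is.data.frame(truth), nrow(truth) == 1)
  p_nc <- truth$p_noncleavage
  p_lp <- truth$p_loxP_given_cleaved
  probs <- c(uncleaved = p_nc,
             loxP_cleaved = (1 - p_nc) * p_lp,
             lox2272_cleaved = (1 - p_nc) * (1 - p_lp))
  with_seed(seed, {
    counts <- as.integer(stats::rmultinom(1, size = truth$n_molecules,
                                          prob = probs))
    stats::setNames(counts, names(probs))
  })
}

# Apply i.i.d. per-base substitution errors to a character vector of reads.
apply_substitution_errors <- function(reads, error_rate) {
  if (error_rate == 0 || length(reads) == 0) return(reads)
  widths <- nchar(reads)
  n_err <- stats::rbinom(length(reads), size = widths, prob = error_rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    chars <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(widths[i], n_err[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(BASES, chars[p]), 1)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Simulate paired-end reads for a truth table (in memory)
#'
#' Each molecule yields one read pair: mate 1 is the first `read_len` bases of
#' its amplicon, mate 2 the reverse complement of the last `read_len` bases
#' (shorter amplicons give shorter reads). Substitution errors are i.i.d. per
#' base; indels are out of scope.
#'
#' @param truth Truth data.frame (rows as in [truth_record()]).
#' @param config A [construct_config()]; defaults to one built from `seed`.
#' @param read_len Read length (bases).
#' @param error_rate Per-base substitution error probability, in \[0, 0.2\].
#' @param seed Integer seed.
#' @return A `data.table` with one row per read pair: `id`, `variant`,
#'   `outcome` (simulated truth), `m1`, `m2`. The construct config is
#'   attached as attribute `"config"`, the truth table as `"truth"`.
#' @export
simulate_read_pairs <- function(truth, config = NULL, read_len = 150L,
                                error_rate = 0, seed = 1L) {
  stopifnot(is.data.frame(truth), nrow(truth) >= 1)
  if (error_rate < 0 || error_rate > 0.2) {
    stop("`error_rate` must be in [0, 0.2]", call. = FALSE)
  }
  if (is.null(config)) config <- construct_config(seed)
  outcome_names <- c("uncleaved", "loxP_cleaved", "lox2272_cleaved")
  with_seed(seed, {
    per_variant <- lapply(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, , drop = FALSE]
      cons <- build_construct(tr$variant, config = config)
      amps <- excision_products(cons)
      counts <- as.integer(stats::rmultinom(
        1, size = tr$n_molecules,
        prob = c(tr$p_noncleavage,
                 (1 - tr$p_noncleavage) * tr$p_loxP_given_cleaved,
                 (1 - tr$p_noncleavage) * (1 - tr$p_loxP_given_cleaved))))
      amp_vec <- c(amps$uncleaved, amps$loxP_product, amps$lox2272_product)
      m1_tpl <- substr(amp_vec, 1L, pmin(nchar(amp_vec), read_len))
      m2_tpl <- revcomp(substr(amp_vec,
                               pmax(1L, nchar(amp_vec) - read_len + 1L),
                               nchar(amp_vec)))
      data.table::data.table(
        variant = tr$variant,
        outcome = rep(outcome_names, counts),
        m1 = rep(m1_tpl, counts),
        m2 = rep(m2_tpl, counts))
    })
    pairs <- data.table::rbindlist(per_variant)
    pairs[, id := sprintf("pair_%07d", .I)]
    data.table::setcolorder(pairs, c("id", "variant", "outcome", "m1", "m2"))
    pairs[, m1 := apply_substitution_errors(m1, error_rate)]
    pairs[, m2 := apply_substitution_errors(m2, error_rate)]
    data.table::setattr(pairs, "config", config)
    data.table::setattr(pairs, "truth", truth)
    pairs[]
  })
}

#' Simulate a sequencing run and write paired FASTQ plus ground truth
#'
#' Writes `reads_R1.fastq`, `reads_R2.fastq` (constant Phred 37 qualities),
#' `truth.tsv` (the per-variant true rates and molecule counts) and
#' `markers.yaml` (anchors and marker tags needed downstream) to `out_dir`.
#'
#' @inheritParams simulate_read_pairs
#' @param out_dir Output directory (created if needed).
#' @param gzip Compress the FASTQ files.
#' @return Invisibly, a named list of the file paths plus the read-pair table.
#' @export
generate_fastq <- function(truth, out_dir, config = NULL, read_len = 150L,
                           error_rate = 0, seed = 1L, gzip = FALSE) {
  if (is.null(config)) config <- construct_config(seed)
  pairs <- simulate_read_pairs(truth, config = config, read_len = read_len,
                               error_rate = error_rate, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  r1_path <- file.path(out_dir, paste0("reads_R1", ext))
  r2_path <- file.path(out_dir, paste0("reads_R2", ext))
  write_fastq <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    qual <- Biostrings::PhredQuality(strrep("F", nchar(seqs)))  # Phred 37
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                                compress = gzip)
  }
  tryCatch({
    write_fastq(pairs$m1, pairs$id, r1_path)
    write_fastq(pairs$m2, pairs$id, r2_path)
  }, error = function(e) {
    stop(sprintf("failed writing FASTQ under %s: %s", out_dir,
                 conditionMessage(e)), call. = FALSE)
  })
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  markers_path <- file.path(out_dir, "markers.yaml")
  write_markers(config, markers_path, read_len = read_len,
                error_rate = error_rate, run_seed = seed)
  invisible(list(r1 = r1_path, r2 = r2_path, truth = truth_path,
                 markers = markers_path, pairs = pairs))
}

#' Write / read the marker configuration
#'
#' The markers file records everything classification needs: the 21-base lox
#' anchors (left RBE + spacer) and the two diagnostic marker tags, plus the
#' run metadata (seed, read length, error rate).
#'
#' @param config A [construct_config()].
#' @param path YAML file path.
#' @param ... Extra scalar metadata stored alongside.
#' @return `write_markers()`: the path, invisibly. `read_markers()`: a
#'   `construct_config`.
#' @export
write_markers <- function(config, path, ...) {
  stopifnot(inherits(config, "construct_config"))
  meta <- list(...)
  yaml::write_yaml(c(unclass(config), meta), path)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  raw <- yaml::read_yaml(path)
  keep <- c("markerA", "markerB", "flank5", "flank3", "stuffer",
            "anchor_loxP", "anchor_lox2272", "seed")
  structure(raw[intersect(keep, names(raw))], class = "construct_config")
}
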