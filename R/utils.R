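# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' Wild-type lox sequence elements
#'
#' Constant accessors for the sequence elements of the two lox sites, written
#' on the analysis (top) strand of the amplicon. A 34-bp lox site is
#' left RBE (13 bp) + spacer (8 bp) + right RBE (13 bp); the right RBE of
#' loxP is the target of mutagenesis in this screen. Note that per-variant
#' tables in the wet-lab convention print the loxP spacer as its reverse
#' complement (GCATACAT); internally everything is top-strand.
#'
#' @return A single character string.
#' @export
wt_rbe <- function() "TATACGAAGTTAT"

#' @rdname wt_rbe
#' @export
left_rbe <- function() "ATAACTTCGTATA"

#' @rdname wt_rbe
#' @export
loxp_spacer <- function() "ATGTATGC"

#' @rdname wt_rbe
#' @export
lox2272_spacer <- function() "AAGTATCC"

#' @rdname wt_rbe
#' @export
loxp_anchor <- function() paste0(left_rbe(), loxp_spacer())

#' @rdname wt_rbe
#' @export
lox2272_anchor <- function() paste0(left_rbe(), lox2272_spacer())

RBE_LEN <- 13L

# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Validate a vector of RBE sequences: exact length, DNA alphabet.
validate_rbe <- function(sequence, len = RBE_LEN) {
  if (!is.character(sequence) || length(sequence) == 0) {
    stop("`sequence` must be a non-empty character vector", call. = FALSE)
  }
  sequence <- toupper(sequence)
  bad_len <- nchar(sequence) != len
  if (any(bad_len)) {
    stop(sprintf("RBE sequences must be exactly %d bases; offending: %s",
                 len, sequence[which(bad_len)[1]]), call. = FALSE)
  }
  bad_chr <- grepl("[^ACGT]", sequence)
  if (any(bad_chr)) {
    stop(sprintf("RBE sequences must use only A/C/G/T; offending: %s",
                 sequence[which(bad_chr)[1]]), call. = FALSE)
  }
  sequence
}

# Reverse complement for plain character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA string(s) from the uniform base distribution.
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

round1 <- function(x) round(x, 1)
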