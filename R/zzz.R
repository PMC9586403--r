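#' @importFrom data.table :=
#' @importFrom stats setNames
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".I", ".N", "id", "idx", "kmer", "m1", "m2", "outcome", "variant",
  "n_reads", "n_uncleaved", "n_loxP_cleaved", "n_lox2272_cleaved",
  "n_unclassified"
))
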