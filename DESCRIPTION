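Package: loxscreen
Title: Quantifying Cre Recombination Efficiency Across Mutant loxP Libraries
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for competitive Cre-lox excision screens of
    mutant loxP sites. Models biased-randomization (doped-oligo) libraries of
    the 13-bp right recombinase-binding element with a binomial
    substitution-count distribution; simulates the competitive
    loxP-versus-lox2272 excision construct and paired-end amplicon reads with
    a ground-truth table; classifies read pairs into non-cleavage,
    loxP-excision and lox2272-excision outcomes by exact anchor and marker
    matching; estimates per-variant cleavage and non-cleavage rates with a
    read-depth cutoff; and cross-validates rates against qPCR standard-curve
    quantification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    data.table,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
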