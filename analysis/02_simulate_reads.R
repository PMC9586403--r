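#!/usr/bin/env Rscript
# Stage 2 — simulate the competitive excision experiment and emit reads.
#
# Takes the distinct variants drawn in stage 1 (capped for runtime), assigns
# each a true loxP-vs-lox2272 cleavage probability from the default affinity
# model (0.5 for WT, decaying 15% per substitution) on top of the 3.5%
# non-cleavage background, and writes paired FASTQ plus the ground truth.

suppressMessages(library(loxscreen))

lib <- read.delim("results/library.tsv")
variants <- unique(lib$variant_sequence)
variants <- variants[seq_len(min(200, length(variants)))]
truth <- default_truth(variants, p_noncleavage = 0.035, decay = 0.85,
                       n_molecules = 2000L)

out <- generate_fastq(truth, "results/sim", config = construct_config(1),
                      read_len = 150L, error_rate = 0.001, seed = 1)
cat(sprintf("simulated %d variants x 2000 molecules -> %d read pairs\n",
            nrow(truth), nrow(out$pairs)))
cat(sprintf("outputs: %s, %s\n  truth: %s\n  markers: %s\n",
            out$r1, out$r2, out$truth, out$markers))
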