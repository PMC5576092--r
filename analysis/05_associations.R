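#!/usr/bin/env Rscript
# Summary tables, the four paired Fisher comparisons plus the downstream-ORF
# t test, and the MuF-family / toxin-domain association network.

suppressPackageStartupMessages(library(mufscan))

ds <- read_dataset("results/dataset")
res <- run_pipeline(ds, outdir = "results/tables")

cat("genomes encoding at least one MuF protein, by dataset:\n")
print(res$summary[res$summary$grouping == "type",
                  c("level", "n_genomes", "n_muf_pos", "prop_muf_pos")])
cat("\npaired association tests:\n")
print(res$tests[, c("test", "p_value", "method")])
cat("\nMuF-family / toxin-domain network (weight = proteins):\n")
print(res$network)
cat("\nall tables written to results/tables\n")
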