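#!/usr/bin/env Rscript
# Candidate immunity ORFs: the gene immediately downstream of each muf gene,
# flagged as small when it encodes < 150 aa, split by architecture class.

suppressPackageStartupMessages(library(mufscan))

ds <- read_dataset("results/dataset")
muf <- call_muf_proteins(ds$hits, ds$genes)
arch <- classify_architecture(muf, ds$hits)
cand <- flag_candidates(arch, ds$genes)

for (cl in c("CT_TOXIN", "CT_UNKNOWN", "SHORT")) {
  sub <- cand[cand$class == cl, ]
  cat(sprintf("%-11s %3d muf genes, %5.1f%% followed by a small ORF\n",
              cl, nrow(sub), 100 * mean(sub$is_small)))
}
lens <- length_distributions(cand)
cat("mean downstream product length (aa):\n")
print(vapply(lens, mean, numeric(1)))

write_results(list(candidates = cand), "results/tables")
cat("wrote results/tables/candidates.tsv\n")
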