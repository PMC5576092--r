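#!/usr/bin/env Rscript
# Screen the domain-hit table for MuF proteins (best-e-value family per
# protein) and classify their C-terminal architecture against the bundled
# toxin-domain catalog.

suppressPackageStartupMessages(library(mufscan))

ds <- read_dataset("results/dataset")
muf <- call_muf_proteins(ds$hits, ds$genes)
arch <- classify_architecture(muf, ds$hits)

cat("MuF proteins called:", nrow(arch), "\n")
cat("by family:\n"); print(table(arch$family))
cat("by architecture (Ct_MAD split out):\n")
print(table(architecture_label(arch)))
ext <- arch[arch$has_extension, ]
cat(sprintf("extended proteins: %d; of these %.1f%% carry a toxin domain\n",
            nrow(ext), 100 * mean(ext$class == "CT_TOXIN")))

write_results(list(muf_proteins = arch), "results/tables")
cat("wrote results/tables/muf_proteins.tsv\n")
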