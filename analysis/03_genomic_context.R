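#!/usr/bin/env Rscript
# Gene-neighbourhood context of muf genes: signed rank distances to
# portal/terminase genes, prophage association of bacterial muf genes, and
# lysogeny of the bacterial strains.

suppressPackageStartupMessages(library(mufscan))

ds <- read_dataset("results/dataset")
muf <- call_muf_proteins(ds$hits, ds$genes)
arch <- classify_architecture(muf, ds$hits)
ctx <- context_profiles(arch, ds$genes, ds$hits, ds$regions, ds$metadata)
lys <- lysogeny_table(ds$metadata, ds$regions)

phage_ctx <- ctx[is.na(ctx$association), ]
bact_ctx <- ctx[!is.na(ctx$association), ]

cat(sprintf("phage muf genes near a packaging gene (+/-10): %.1f%% of %d\n",
            100 * mean(phage_ctx$near_packaging), nrow(phage_ctx)))
cat("muf offset from the nearest portal gene (phage genomes):\n")
print(table(phage_ctx$portal_offset_of_muf, useNA = "ifany"))
cat("bacterial muf association categories:\n")
print(table(bact_ctx$association))
cat(sprintf("prophage-associated bacterial muf genes: %.1f%%\n",
            100 * mean(bact_ctx$association != "UNASSOCIATED")))
bact <- lys[lys$type == "bacterium", ]
cat(sprintf("lysogenic strains: %.1f%% of %d\n",
            100 * mean(bact$lysogen), nrow(bact)))

write_results(list(contexts = ctx, lysogeny = lys), "results/tables")
cat("wrote results/tables/{contexts,lysogeny}.tsv\n")
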