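---
title: "Mining MuF polymorphic toxins from domain-hit tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining MuF polymorphic toxins from domain-hit tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mufscan)
```

## The problem

Polymorphic toxins (PTs) are modular bacterial exotoxins: a conserved
N-terminal family domain fused to a variable C-terminal toxin domain drawn
from a pool shared across PT families, usually with a small immunity protein
encoded immediately downstream of the toxin gene. The MuF family is unusual
among PTs in being phage-borne: MuF-domain proteins (named after protein F of
phage Mu) sit in the DNA-packaging module of tailed phages, typically next to
the portal gene, and a fraction of them carry a C-terminal toxin extension.

`mufscan` implements the comparative-genomics pipeline that characterises
this family from standard intermediate artefacts — per-genome gene annotation
tables, HMMER3 per-domain hit tables (`--domtblout`, scanned with the
profiles' GA gathering thresholds), and prophage region tables from an
external detector. It does **not** build HMM profiles, run the scans, or
detect prophages; those live upstream and their outputs are this package's
inputs.

## The procedure

1. **Screening** (`call_muf_proteins`). Every protein with at least one
   GA-passing MuF-class hit (MuF1 = Phage_Mu_F/PF04233, MuF2 =
   Phage_min_cap2/PF06152, plus the context-defined MuF3 and MuF4) becomes
   one MuF protein. When several MuF profiles hit the same protein, the
   family is the profile with the smallest full-sequence E-value, ties broken
   by higher bitscore, then lexicographic profile name. We rank by the
   full-sequence E-value rather than the per-domain conditional E-value: the
   selection is per protein, and the full-sequence statistic is the natural
   per-protein ranking. A protein with two envelopes of the same family is
   counted once, with the envelope of the better hit.

2. **Architecture** (`classify_architecture`). The C-terminal extension is
   measured from the end of the MuF domain envelope to the protein's
   C-terminus; an extension of ≥ 100 aa counts as present (the shortest
   toxin-bearing extension observed in the family is 113 aa, so the cutoff
   leaves headroom without absorbing linkers). Envelope coordinates are used
   because they are the defensible domain boundary in a domtblout;
   alignment coordinates would shrink the extension slightly and are noted as
   a sensitivity, not implemented. A protein is `CT_TOXIN` when a catalog
   toxin domain's envelope *midpoint* lies inside the extension (midpoints
   are robust to small envelope overlaps at the MuF boundary), otherwise
   `CT_UNKNOWN`, with the Ct_MAD subtype flagged when a Ct_MAD hit lies in
   the extension; without an extension it is `SHORT`. Toxin hits N-terminal
   of the MuF domain never determine the class — the classes are defined on
   the C-terminal region.

3. **Genomic context** (`context_profiles`). For each muf gene we compute
   the signed gene-rank distance (`marker_rank − muf_rank`, strand-agnostic,
   ties between −k and +k resolved to +k) to the nearest portal, terminase
   large subunit and terminase small subunit gene within ±10 genes. The
   window is positional, not transcriptional, and replicons are treated as
   linear. Because packaging modules are usually described from the portal
   gene's point of view, the context table also reports
   `portal_offset_of_muf = −d_portal`, the orientation in which "muf at +1
   of the portal gene" reads naturally.

4. **Prophage association** (`assign_association`). A bacterial muf gene
   whose midpoint lies in a detected region **longer than 18 kb** is in a
   prophage; in a region of at most 18 kb, in a remnant (exactly 18,000 bp
   is a remnant — the prophage definition is strict "larger than"); outside
   any region but within the ±10-gene window of a packaging marker, near
   packaging genes (the remnant rule reuses the only stated window); else
   unassociated. Midpoints avoid double-assigning boundary-spanning genes;
   when regions of both size classes contain a gene the largest wins, with a
   warning. A strain is a lysogen when it carries ≥ 1 region > 18 kb.

5. **Immunity candidates** (`flag_candidates`). The gene immediately
   downstream of each muf gene in its transcription orientation (rank+1 on
   `+`, rank−1 on `−`; none at linear replicon ends) is a small-ORF
   candidate when it encodes **strictly fewer than 150 aa**. Co-orientation
   and the intergenic gap are reported but not required — the analysis
   counts genes annotated immediately downstream without a strand filter,
   and no maximum gap is imposed; both are in the output so users can
   filter.

6. **Statistics** (`fisher_exact_two_tailed`, `two_sample_t`,
   `paired_association_tests`, `build_network`, `summarize_groups`). The
   two-tailed Fisher test sums hypergeometric probabilities of all tables
   (fixed margins) with probability ≤ the observed table's, within relative
   tolerance 1e-7 — the convention of R's reference implementation, which
   this analysis tradition uses. The t test defaults to Welch (the reference
   implementation's default) with a pooled-variance option; the output
   labels which was used. Raw p-values are reported; no multiplicity
   correction is applied, matching the analysis style, and users can apply
   `p.adjust` downstream. The family/toxin-domain network keeps one weighted
   edge per (MuF family, toxin domain) pair, dropping toxin domains carried
   by fewer than five MuF proteins in total.

## Thresholds

All cutoffs live in a single `default_thresholds()` object:

| parameter | default | unit | role |
|---|---|---|---|
| `ct_extension_min` | 100 | aa | extension present (inclusive) |
| `small_orf_max` | 150 | aa | small ORF (strict `<`) |
| `prophage_min` | 18,000 | bp | prophage vs remnant (strict `>`) |
| `context_window` | 10 | genes | marker distances and the "near" rule |
| `network_min_support` | 5 | proteins | network edge filter |

## The synthetic-data generator

Real inputs for this analysis are genome-scale scans that cannot be shipped;
`generate_dataset()` instead draws datasets with the statistical structure
the pipeline assumes, plus per-gene/per-genome ground truth, so every stage
is testable end to end. Its defaults are the study regime: 35% of phages
carry a muf gene; the architecture mix is 62% short, 13% toxin, 17% unknown
extension, 8% Ct_MAD (equivalently, 34% of extended proteins carry a toxin
and a third of unknown extensions carry Ct_MAD); small ORFs follow 89.4% of
toxin genes and 25.5% of short-MuF genes (the unknown/Ct_MAD classes reuse
the short-MuF rate, which is unstated elsewhere); 96% of bacterial muf genes
are prophage-associated (90/3/3/4 across the four categories); 50% of
strains are lysogens; the muf gene sits at +1 of the portal with probability
0.65 (mass concentrated at +1); phage families split 50/26/19/5
Sipho/Myo/Podo/non-tailed, with muf genes enriched in Siphoviridae and
temperate phages and toxin architectures in Firmicutes unless
`null_effects = TRUE` severs all such couplings.

Construction choices that make the thresholds discriminative by design:
background gene lengths are log-normal around 300 aa; planted immunity ORFs
are uniform on [50, 149] aa and decoy downstream genes on [150, 500] aa;
planted hits draw E-values in [1e-30, 1e-15], cross-family decoy MuF hits in
[1e-12, 1e-8] (so best-hit selection is exercised with a deterministic
winner), and spurious hits in [1e-4, 1]. Prophage lengths are drawn from a
range that straddles 18 kb so both size classes occur; a muf-free large
prophage is added at the conditional rate that makes overall lysogeny equal
`p_prophage`. One muf gene per genome is planted (the family is near-unique
per genome in practice); a `multi_muf` flag exists for the exception path.

What the generator does **not** emulate: nucleotide sequences, real
inter-gene length correlations, partial or nested packaging modules, muf
genes outside any module context (every planted phage muf sits in a complete
portal+terminase module, so packaging adjacency is ~100% here, higher than
on real data), mosaic prophages, and taxonomic structure beyond labelled
clade strings. Passing tests therefore demonstrate the pipeline's logic and
calibration, not performance on real annotation noise.

## Numerical and degenerate-input choices

Internal coordinates are 0-based half-open with a single conversion site at
the I/O boundary (annotation tables and GFF3 are 1-based inclusive); protein
length comes from an explicit `aa_length` column when present, else
`(span/3) − 1` for a stop-inclusive CDS. Zero-margin 2×2 tables give Fisher
p = 1 with a warning; degenerate t-test samples are an error. Empty inputs
flow through: header-only tables in, header-only tables out. Tie-breaks are
total orders (E-value, then bitscore, then profile name; +k over −k), so
every result is deterministic and output files are byte-stable for a given
input and seed; the run manifest records the seed, thresholds and input
sizes rather than wall-clock timestamps, which would break byte-identical
reproduction.

## Problem sizes

The packaged analyses and checks run at desk scale, chosen so the full suite
completes in a few minutes: the narrative workflow under `analysis/` uses
600 phage + 400 bacterial genomes; exactness checks use 200+200 genomes with
a noise-free hit table; calibration checks use 1,000 genomes; the
null-behaviour study uses 100 replicates of 500 genomes; the Fisher
implementation is swept exhaustively against enumeration for all 2×2 tables
with N ≤ 30. Bacterial chromosomes average 250 genes — an order of magnitude
below real chromosomes, which only dilutes per-genome muf density and does
not affect any windowed statistic.

## Known limitations

* The pipeline consumes GA-filtered hit tables; it cannot rescue hits the
  upstream scan discarded, and in raw mode it applies no per-profile GA
  table of its own (hits must be re-filtered by the caller).
* Circular replicons are treated as linear for ranks and adjacency; genes at
  the origin can lose a neighbour.
* The bundled toxin-domain catalog is a compact stand-in covering the
  activities most often fused to MuF extensions; real mining should supply
  the full catalog via `toxin_catalog_from_table()`.
* `CT_UNKNOWN` is a negative category: it shrinks, never grows, as the
  catalog improves (monotonicity is tested).
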