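# Synthetic genome/hit-table generator.
#
# Emulates the statistical structure the MuF analysis assumes: tailed phages
# whose DNA-packaging module (terminase small/large subunit, portal) carries a
# muf gene next to the portal gene; bacterial chromosomes with prophages
# (> 18 kb), remnants and free-standing packaging clusters; a configurable mix
# of MuF architectures; small ORFs planted downstream of muf genes; and
# background genes plus spurious domain hits. Every draw is governed by the
# spec's seed, so a given spec is a reproducible study condition.

ARCH_CLASSES <- c("SHORT", "CT_TOXIN", "CT_UNKNOWN", "CT_MAD")
ASSOC_CLASSES <- c("IN_PROPHAGE", "IN_REMNANT", "NEAR_PACKAGING", "UNASSOCIATED")

#' Specification of a synthetic MuF dataset
#'
#' Collects every parameter of the generator. The defaults are the regime the
#' analysis targets: 35% of tailed phages carry a muf gene, 13% of MuF
#' proteins carry a C-terminal toxin domain (with 34% of extended proteins
#' toxin-bearing and a third of unknown extensions carrying Ct_MAD), small
#' downstream ORFs follow 89.4% of toxin genes and 25.5% of short-MuF genes,
#' half of bacterial strains are lysogens, 96% of bacterial muf genes are
#' prophage-associated, and the muf gene sits at +1 of the portal gene in
#' most packaging modules.
#'
#' @param seed integer; fixes every random draw.
#' @param n_phage_genomes,n_bacterial_genomes dataset sizes.
#' @param p_muf_phage probability a phage carries a packaging module with a
#'   muf gene.
#' @param p_muf_bacterium probability a bacterial chromosome carries a muf
#'   gene.
#' @param p_prophage probability a bacterial genome is lysogenic (carries at
#'   least one large prophage, muf-bearing or not).
#' @param prophage_len_range length range (bp) for planted regions; must
#'   straddle 18,000 bp so that both prophages and remnants can be drawn.
#' @param architecture_mix named probabilities over
#'   SHORT/CT_TOXIN/CT_UNKNOWN/CT_MAD; must sum to 1.
#' @param assoc_mix named probabilities over the prophage-association
#'   categories of bacterial muf genes.
#' @param p_small_orf_given_toxin,p_small_orf_given_short,p_small_orf_given_unknown
#'   probability that the gene downstream of a muf gene encodes < 150 aa,
#'   by muf architecture.
#' @param muf_offset_dist named probabilities over signed gene-rank offsets
#'   of the muf gene from the portal gene (names are the offsets; no 0).
#' @param p_false_hit per-protein probability of a spurious domain hit.
#' @param p_second_muf_hit probability a planted MuF protein also carries a
#'   weaker cross-family MuF hit (exercises best-profile selection).
#' @param mean_genes_per_genome mean gene count of a phage genome.
#' @param mean_genes_per_bacterium mean gene count of a bacterial chromosome.
#' @param muf_family_mix named probabilities over MUF1..MUF4.
#' @param family_mix phage taxonomic family mix (Siphoviridae, Myoviridae,
#'   Podoviridae, NonCaudovirales).
#' @param clade_mix host/bacterial clade mix.
#' @param p_lifestyle_labeled fraction of phages with a confident lifestyle
#'   label.
#' @param null_effects when `TRUE`, clade, phage family and lifestyle are
#'   drawn independently of muf content (for null-behaviour studies);
#'   when `FALSE`, muf and toxin genes are enriched in Siphoviridae,
#'   temperate phages and Firmicutes as in the study regime.
#' @param multi_muf allow a second muf module in a phage genome (rare path).
#' @return object of class `muf_synth_spec`.
#' @export
synthetic_spec <- function(seed,
                           n_phage_genomes = 200L,
                           n_bacterial_genomes = 200L,
                           p_muf_phage = 0.35,
                           p_muf_bacterium = 0.25,
                           p_prophage = 0.5,
                           prophage_len_range = c(8000L, 45000L),
                           architecture_mix = c(SHORT = 0.62, CT_TOXIN = 0.13,
                                                CT_UNKNOWN = 0.17, CT_MAD = 0.08),
                           assoc_mix = c(IN_PROPHAGE = 0.90, IN_REMNANT = 0.03,
                                         NEAR_PACKAGING = 0.03, UNASSOCIATED = 0.04),
                           p_small_orf_given_toxin = 0.894,
                           p_small_orf_given_short = 0.255,
                           p_small_orf_given_unknown = 0.255,
                           muf_offset_dist = c("1" = 0.65, "2" = 0.12,
                                               "-1" = 0.10, "3" = 0.08,
                                               "-2" = 0.05),
                           p_false_hit = 0.01,
                           p_second_muf_hit = 0.25,
                           mean_genes_per_genome = 60L,
                           mean_genes_per_bacterium = 250L,
                           muf_family_mix = c(MUF1 = 0.55, MUF2 = 0.20,
                                              MUF3 = 0.15, MUF4 = 0.10),
                           family_mix = c(Siphoviridae = 0.50, Myoviridae = 0.26,
                                          Podoviridae = 0.19, NonCaudovirales = 0.05),
                           clade_mix = c(Firmicutes = 0.35, Proteobacteria = 0.40,
                                         Actinobacteria = 0.15, Other = 0.10),
                           p_lifestyle_labeled = 0.55,
                           null_effects = FALSE,
                           multi_muf = FALSE) {
  if (missing(seed) || is.null(seed)) {
    stop("an explicit integer seed is required for reproducibility")
  }
  spec <- list(
    seed = as.integer(seed),
    n_phage_genomes = as.integer(n_phage_genomes),
    n_bacterial_genomes = as.integer(n_bacterial_genomes),
    p_muf_phage = p_muf_phage,
    p_muf_bacterium = p_muf_bacterium,
    p_prophage = p_prophage,
    prophage_len_range = as.integer(prophage_len_range),
    architecture_mix = architecture_mix,
    assoc_mix = assoc_mix,
    p_small_orf_given_toxin = p_small_orf_given_toxin,
    p_small_orf_given_short = p_small_orf_given_short,
    p_small_orf_given_unknown = p_small_orf_given_unknown,
    muf_offset_dist = muf_offset_dist,
    p_false_hit = p_false_hit,
    p_second_muf_hit = p_second_muf_hit,
    mean_genes_per_genome = as.integer(mean_genes_per_genome),
    mean_genes_per_bacterium = as.integer(mean_genes_per_bacterium),
    muf_family_mix = muf_family_mix,
    family_mix = family_mix,
    clade_mix = clade_mix,
    p_lifestyle_labeled = p_lifestyle_labeled,
    null_effects = isTRUE(null_effects),
    multi_muf = isTRUE(multi_muf)
  )
  validate_spec(spec)
  class(spec) <- "muf_synth_spec"
  spec
}

validate_spec <- function(spec) {
  probs <- c(spec$p_muf_phage, spec$p_muf_bacterium, spec$p_prophage,
             spec$p_small_orf_given_toxin, spec$p_small_orf_given_short,
             spec$p_small_orf_given_unknown, spec$p_false_hit,
             spec$p_second_muf_hit, spec$p_lifestyle_labeled)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  for (nm in c("architecture_mix", "assoc_mix", "muf_family_mix",
               "family_mix", "clade_mix", "muf_offset_dist")) {
    mix <- spec[[nm]]
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
      stop(nm, " must be non-negative and sum to 1")
    }
  }
  if (!setequal(names(spec$architecture_mix), ARCH_CLASSES)) {
    stop("architecture_mix must name exactly ", paste(ARCH_CLASSES, collapse = ", "))
  }
  if (!setequal(names(spec$assoc_mix), ASSOC_CLASSES)) {
    stop("assoc_mix must name exactly ", paste(ASSOC_CLASSES, collapse = ", "))
  }
  off <- as.integer(names(spec$muf_offset_dist))
  if (anyNA(off) || any(off == 0L)) {
    stop("muf_offset_dist names must be non-zero signed integer offsets")
  }
  if (any(abs(off) > 4L)) {
    stop("muf offsets beyond |4| do not fit the packaging-module layout")
  }
  lo <- spec$prophage_len_range[[1]]; hi <- spec$prophage_len_range[[2]]
  if (lo >= hi) stop("prophage_len_range must be increasing")
  need_remnant <- spec$assoc_mix[["IN_REMNANT"]] > 0
  need_prophage <- spec$assoc_mix[["IN_PROPHAGE"]] > 0 || spec$p_prophage > 0
  if (need_remnant && lo >= 18000L) {
    stop("prophage_len_range must straddle 18 kb to draw remnants (< 18 kb)")
  }
  if (need_prophage && hi <= 18000L) {
    stop("prophage_len_range must straddle 18 kb to draw prophages (> 18 kb)")
  }
  invisible(spec)
}

# profile names used for planted hits, per class
GEN_PROFILES <- list(
  MUF1 = "MuF1", MUF2 = "MuF2", MUF3 = "MuF3", MUF4 = "MuF4",
  CT_MAD = "Ct_MAD", PORTAL = "Phage_portal", TLS = "Terminase_GpA",
  TSS = "Terminase_2"
)
DECOY_PROFILES <- c("DUF4043", "HTH_XRE", "Phage_tail_S")

sample1 <- function(x, prob = NULL) {
  if (length(x) == 1L) return(x)
  x[sample.int(length(x), 1L, prob = prob)]
}

rlen_aa <- function(n) {
  pmin(pmax(as.integer(round(stats::rlnorm(n, log(300), 0.35))), 50L), 2000L)
}

planted_evalue <- function(n) 10^stats::runif(n, -30, -15)
decoy_evalue <- function(n) 10^stats::runif(n, -12, -8)
spurious_evalue <- function(n) stats::runif(n, 1e-4, 1)

# Lay out a packaging module around a portal slot. Returns integer 1-based
# gene indices for portal, muf, the gene downstream of muf (in transcription
# orientation; muf goes on '-' strand for negative offsets so the downstream
# slot never collides with the portal), and the TLS/TSS slots.
module_layout <- function(portal_idx, offset) {
  muf_idx <- portal_idx + offset
  muf_strand <- if (offset > 0L) "+" else "-"
  down_idx <- if (offset > 0L) muf_idx + 1L else muf_idx - 1L
  candidates <- portal_idx + c(1L, -1L, 2L, -2L, 3L, -3L, 4L, -4L)
  candidates <- setdiff(candidates, c(portal_idx, muf_idx, down_idx))
  list(portal = portal_idx, muf = muf_idx, down = down_idx,
       muf_strand = muf_strand, tls = candidates[[1]], tss = candidates[[2]])
}

# Draw the MuF protein itself: envelope, extension, architecture-dependent
# extra hits. Returns aa length, envelope, and a list of hit rows.
draw_muf_protein <- function(arch, family, protein_id, spec, toxin_names) {
  env_from <- sample.int(20L, 1L)
  env_to <- env_from + sample(140:260, 1L)
  ext <- if (arch == "SHORT") sample(0:90, 1L) else sample(100:400, 1L)
  aa_len <- env_to + ext
  hits <- list(list(protein_id = protein_id,
                    profile_name = GEN_PROFILES[[family]],
                    full_evalue = planted_evalue(1L),
                    bitscore = stats::runif(1L, 150, 400),
                    env_from = env_from, env_to = env_to))
  if (stats::runif(1L) < spec$p_second_muf_hit) {
    other <- sample1(setdiff(names(spec$muf_family_mix), family))
    shift <- sample.int(10L, 1L)
    hits[[length(hits) + 1L]] <- list(
      protein_id = protein_id, profile_name = GEN_PROFILES[[other]],
      full_evalue = decoy_evalue(1L), bitscore = stats::runif(1L, 30, 120),
      env_from = env_from + shift, env_to = env_to + shift)
  }
  if (arch %in% c("CT_TOXIN", "CT_MAD")) {
    dom_from <- env_to + max(1L, ext %/% 5L)
    dom_to <- min(aa_len, dom_from + sample(40:70, 1L))
    nm <- if (arch == "CT_TOXIN") sample1(toxin_names) else GEN_PROFILES$CT_MAD
    hits[[length(hits) + 1L]] <- list(
      protein_id = protein_id, profile_name = nm,
      full_evalue = planted_evalue(1L), bitscore = stats::runif(1L, 60, 200),
      env_from = dom_from, env_to = dom_to)
  }
  list(aa_len = aa_len, hits = hits)
}

marker_hit <- function(protein_id, class, aa_len) {
  list(protein_id = protein_id, profile_name = GEN_PROFILES[[class]],
       full_evalue = planted_evalue(1L), bitscore = stats::runif(1L, 120, 350),
       env_from = 5L, env_to = as.integer(min(aa_len, 5L + 300L)))
}

draw_cond <- function(mix, shift = NULL) {
  # shift: named vector replacing the mix under study-regime effects
  if (is.null(shift)) sample1(names(mix), prob = mix) else sample1(names(shift), prob = shift)
}

# Generate one genome. Returns lists of per-gene vectors and hit rows plus
# truth labels; assembled into data.frames by generate_dataset().
gen_genome <- function(kind, genome_id, spec, toxin_names) {
  n_mean <- if (kind == "phage") spec$mean_genes_per_genome else spec$mean_genes_per_bacterium
  n_floor <- if (kind == "phage") 25L else 60L
  n <- max(n_floor, stats::rpois(1L, n_mean))
  aa <- rlen_aa(n)
  strand <- sample(c("+", "-"), n, replace = TRUE, prob = c(0.8, 0.2))
  product <- rep("hypothetical protein", n)

  replicon <- if (kind == "phage") genome_id else paste0(genome_id, "_chr")
  has_muf <- stats::runif(1L) < (if (kind == "phage") spec$p_muf_phage else spec$p_muf_bacterium)
  assoc <- NA_character_
  arch <- NA_character_
  family <- NA_character_
  small <- NA
  muf_idx <- NA_integer_
  hits <- list()
  lay <- NULL

  if (has_muf) {
    if (kind == "bacterium") assoc <- sample1(ASSOC_CLASSES, prob = spec$assoc_mix)
    family <- sample1(names(spec$muf_family_mix), prob = spec$muf_family_mix)
    arch <- sample1(ARCH_CLASSES, prob = spec$architecture_mix)
    offset <- as.integer(sample1(names(spec$muf_offset_dist),
                                 prob = spec$muf_offset_dist))
    hi_anchor <- if (kind == "phage") n - 8L else max(14L, n %/% 2L - 6L)
    portal_idx <- sample(7:hi_anchor, 1L)
    lay <- module_layout(portal_idx, offset)
    muf_idx <- lay$muf

    if (is.na(assoc) || assoc != "UNASSOCIATED") {
      # full packaging module: portal + both terminase subunits
      aa[lay$portal] <- sample(400:550, 1L)
      aa[lay$tls] <- sample(500:650, 1L)
      aa[lay$tss] <- sample(140:200, 1L)
      strand[c(lay$portal, lay$tls, lay$tss)] <- "+"
      product[lay$portal] <- "phage portal protein"
      product[lay$tls] <- "terminase large subunit"
      product[lay$tss] <- "terminase small subunit"
      hits <- c(hits, list(marker_hit(gene_name(genome_id, lay$portal), "PORTAL", aa[lay$portal]),
                           marker_hit(gene_name(genome_id, lay$tls), "TLS", aa[lay$tls]),
                           marker_hit(gene_name(genome_id, lay$tss), "TSS", aa[lay$tss])))
    }
    strand[muf_idx] <- lay$muf_strand
    product[muf_idx] <- "MuF-domain protein"
    mp <- draw_muf_protein(arch, family, gene_name(genome_id, muf_idx), spec, toxin_names)
    aa[muf_idx] <- mp$aa_len
    hits <- c(hits, mp$hits)

    # plant the gene downstream of the muf gene: immunity-sized or decoy
    p_small <- switch(arch,
                      CT_TOXIN = spec$p_small_orf_given_toxin,
                      SHORT = spec$p_small_orf_given_short,
                      spec$p_small_orf_given_unknown)
    small <- stats::runif(1L) < p_small
    aa[lay$down] <- if (small) sample(50:149, 1L) else sample(150:500, 1L)
    strand[lay$down] <- if (stats::runif(1L) < 0.8) lay$muf_strand else
      setdiff(c("+", "-"), lay$muf_strand)
    product[lay$down] <- if (small) "hypothetical small protein" else "hypothetical protein"
  }

  # coordinates: sequential CDS with small intergenic gaps (internal 0-based)
  nt <- (aa + 1L) * 3L
  gaps <- sample(20:200, n, replace = TRUE)
  start <- cumsum(c(0L, nt[-n] + gaps[-n]))
  end <- start + nt

  regions <- list()
  if (kind == "bacterium") {
    if (has_muf && assoc %in% c("IN_PROPHAGE", "IN_REMNANT")) {
      lo <- spec$prophage_len_range[[1]]; hi <- spec$prophage_len_range[[2]]
      L <- if (assoc == "IN_PROPHAGE") {
        sample(seq.int(max(18001L, lo), hi), 1L)
      } else {
        sample(seq.int(lo, min(18000L, hi)), 1L)
      }
      mid <- (start[muf_idx] + end[muf_idx]) %/% 2L
      rs <- max(0L, mid - L %/% 2L)
      regions[[1L]] <- list(genome_id = genome_id, replicon_id = replicon,
                            start = rs, end = rs + L)
    }
    # p_prophage is the overall lysogeny probability; genomes whose muf gene
    # already sits in a large prophage are lysogens, the rest draw a muf-free
    # large prophage at the complementary conditional rate
    has_muf_prophage <- has_muf && identical(assoc, "IN_PROPHAGE")
    p_mp <- spec$p_muf_bacterium * spec$assoc_mix[["IN_PROPHAGE"]]
    p_extra <- if (p_mp >= 1) 0 else
      max(0, (spec$p_prophage - p_mp) / (1 - p_mp))
    if (!has_muf_prophage && stats::runif(1L) < p_extra) {
      # muf-free large prophage in the distal half of the chromosome
      # (never contains the planted muf gene)
      lo <- max(18001L, spec$prophage_len_range[[1]])
      L <- sample(seq.int(lo, max(lo + 1L, spec$prophage_len_range[[2]])), 1L)
      anchor <- min(n, as.integer(ceiling(0.62 * n)))
      regions[[length(regions) + 1L]] <- list(
        genome_id = genome_id, replicon_id = replicon,
        start = start[anchor], end = start[anchor] + L)
    }
  }

  # spurious hits on random proteins, e-values above the planted range
  n_false <- stats::rbinom(1L, n, spec$p_false_hit)
  if (n_false > 0L) {
    idx <- sample.int(n, n_false)
    # GA-filtered scans do not produce spurious MuF-family calls on random
    # proteins; spurious MuF hits only land on genuine MuF proteins, where
    # they exercise best-profile ranking
    muf_profiles <- unlist(GEN_PROFILES[c("MUF1", "MUF2", "MUF3", "MUF4")],
                           use.names = FALSE)
    full_pool <- c(unlist(GEN_PROFILES, use.names = FALSE), toxin_names,
                   DECOY_PROFILES)
    bg_pool <- setdiff(full_pool, muf_profiles)
    for (i in idx) {
      pool <- if (!is.na(muf_idx) && i == muf_idx) full_pool else bg_pool
      f <- max(1L, sample.int(max(1L, aa[i] - 60L), 1L))
      hits[[length(hits) + 1L]] <- list(
        protein_id = gene_name(genome_id, i), profile_name = sample1(pool),
        full_evalue = spurious_evalue(1L), bitscore = stats::runif(1L, 10, 25),
        env_from = f, env_to = as.integer(min(aa[i], f + sample(30:80, 1L))))
    }
  }

  # genome-level metadata
  lysogen <- NA
  phage_family <- NA_character_
  lifestyle <- NA_character_
  if (kind == "phage") {
    if (spec$null_effects || !has_muf) {
      phage_family <- sample1(names(spec$family_mix), prob = spec$family_mix)
    } else {
      phage_family <- sample1(c("Siphoviridae", "Myoviridae", "Podoviridae"),
                              prob = c(0.86, 0.11, 0.03))
    }
    if (stats::runif(1L) < spec$p_lifestyle_labeled) {
      p_temp <- if (spec$null_effects) 0.6 else if (!has_muf) 0.45 else
        if (identical(arch, "CT_TOXIN")) 0.98 else 0.90
      lifestyle <- if (stats::runif(1L) < p_temp) "temperate" else "virulent"
    }
  } else {
    lysogen <- any(vapply(regions, function(r) (r$end - r$start) > 18000L, logical(1)))
  }
  if (spec$null_effects || !has_muf) {
    clade <- sample1(names(spec$clade_mix), prob = spec$clade_mix)
  } else {
    clade <- switch(arch,
      CT_TOXIN = sample1(names(spec$clade_mix), prob = c(0.80, 0.05, 0.10, 0.05)),
      CT_UNKNOWN = ,
      CT_MAD = sample1(names(spec$clade_mix), prob = c(0.10, 0.70, 0.10, 0.10)),
      sample1(names(spec$clade_mix), prob = spec$clade_mix))
  }

  list(
    genes = list(gene_id = gene_name(genome_id, seq_len(n)),
                 genome_id = rep(genome_id, n), replicon_id = rep(replicon, n),
                 start = start, end = end, strand = strand,
                 aa_length = aa, product_label = product),
    hits = hits,
    regions = regions,
    truth_gene = if (has_muf) list(
      gene_id = gene_name(genome_id, muf_idx), genome_id = genome_id,
      family = family, architecture = arch,
      planted_immunity = small, association = assoc,
      near_packaging = is.na(assoc) || assoc != "UNASSOCIATED") else NULL,
    truth_genome = list(genome_id = genome_id, type = kind,
                        has_muf = has_muf, lysogen = lysogen,
                        clade = clade, phage_family = phage_family,
                        lifestyle = lifestyle)
  )
}

gene_name <- function(genome_id, i) sprintf("%s_g%04d", genome_id, i)

#' Generate a synthetic MuF dataset with ground truth
#'
#' Draws phage and bacterial genome annotations, a domain-hit table in the
#' classes the pipeline consumes, prophage regions and genome metadata, all
#' under the study conditions encoded in `spec`, together with per-gene and
#' per-genome ground-truth labels.
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `muf_dataset`: list with elements `spec`, `genes`,
#'   `hits`, `regions`, `metadata`, `truth_genes`, `truth_genomes`.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_spec(seed = 1, n_phage_genomes = 5,
#'                                       n_bacterial_genomes = 5))
#' nrow(ds$genes)
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "muf_synth_spec"))
  set.seed(spec$seed)
  toxin_names <- default_toxin_catalog()$name
  ids <- c(sprintf("PHG%04d", seq_len(spec$n_phage_genomes)),
           sprintf("BAC%04d", seq_len(spec$n_bacterial_genomes)))
  kinds <- rep(c("phage", "bacterium"),
               c(spec$n_phage_genomes, spec$n_bacterial_genomes))
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    out[[i]] <- gen_genome(kinds[[i]], ids[[i]], spec, toxin_names)
  }

  genes <- data.table::setDF(data.table::rbindlist(lapply(out, `[[`, "genes")))
  genes <- assign_ranks(genes)
  genes <- genes[, GENE_COLUMNS]

  hit_rows <- unlist(lapply(out, `[[`, "hits"), recursive = FALSE)
  hits <- if (length(hit_rows)) {
    h <- data.table::setDF(data.table::rbindlist(hit_rows))
    h$env_from <- as.integer(h$env_from)
    h$env_to <- as.integer(h$env_to)
    h$profile_class <- classify_profiles(h$profile_name,
                                         default_profile_class_map(toxin_names))
    h$passed_ga <- TRUE
    h[, DOMHIT_COLUMNS]
  } else {
    empty_domhit_table()
  }

  region_rows <- unlist(lapply(out, `[[`, "regions"), recursive = FALSE)
  regions <- if (length(region_rows)) {
    r <- data.table::setDF(data.table::rbindlist(region_rows))
    r$length <- r$end - r$start
    r
  } else {
    data.frame(genome_id = character(), replicon_id = character(),
               start = integer(), end = integer(), length = integer(),
               stringsAsFactors = FALSE)
  }

  truth_genes <- data.table::setDF(data.table::rbindlist(
    Filter(Negate(is.null), lapply(out, `[[`, "truth_gene"))))
  if (!nrow(truth_genes)) {
    truth_genes <- data.frame(gene_id = character(), genome_id = character(),
                              family = character(), architecture = character(),
                              planted_immunity = logical(),
                              association = character(),
                              near_packaging = logical(),
                              stringsAsFactors = FALSE)
  }
  truth_genomes <- data.table::setDF(data.table::rbindlist(
    lapply(out, `[[`, "truth_genome")))
  metadata <- truth_genomes[, c("genome_id", "type", "clade", "phage_family",
                                "lifestyle")]

  structure(list(spec = spec, genes = genes, hits = hits, regions = regions,
                 metadata = metadata, truth_genes = truth_genes,
                 truth_genomes = truth_genomes),
            class = "muf_dataset")
}

#' @export
print.muf_dataset <- function(x, ...) {
  cat("Synthetic MuF dataset (seed ", x$spec$seed, ")\n",
      "  genomes: ", sum(x$metadata$type == "phage"), " phage + ",
      sum(x$metadata$type == "bacterium"), " bacterial\n",
      "  genes: ", nrow(x$genes), ";  domain hits: ", nrow(x$hits),
      ";  prophage regions: ", nrow(x$regions), "\n",
      "  planted muf genes: ", nrow(x$truth_genes), "\n", sep = "")
  invisible(x)
}

# ---- on-disk round trip -----------------------------------------------------

#' Write a dataset bundle to disk
#'
#' Emits the exact dialects the readers consume: `genes.tsv` (1-based
#' inclusive annotation table), `hits.domtblout` (HMMER3 per-domain layout),
#' `prophages.tsv` (0-based half-open regions), `metadata.tsv`, and the two
#' ground-truth tables. Output is byte-deterministic for a given dataset.
#'
#' @param ds a `muf_dataset`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "muf_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gene_table(ds$genes, file.path(dir, "genes.tsv"))
  write_domtblout(ds$hits, file.path(dir, "hits.domtblout"))
  write_tsv_deterministic(ds$regions[, c("genome_id", "replicon_id", "start", "end")],
                          file.path(dir, "prophages.tsv"))
  write_tsv_deterministic(ds$metadata, file.path(dir, "metadata.tsv"))
  write_tsv_deterministic(ds$truth_genes, file.path(dir, "truth_genes.tsv"))
  write_tsv_deterministic(ds$truth_genomes, file.path(dir, "truth_genomes.tsv"))
  invisible(dir)
}

#' Write domain hits in HMMER3 domtblout layout
#'
#' @param hits domain-hit data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_domtblout <- function(hits, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target"),
    con)
  if (nrow(hits)) {
    lines <- sprintf(
      "%s - %d %s - %d %.3g %.1f 0.0 1 1 %.3g %.3g %.1f 0.0 1 %d %d %d %d %d 0.90 -",
      hits$protein_id, hits$env_to + 50L, hits$profile_name, 300L,
      hits$full_evalue, hits$bitscore, hits$full_evalue, hits$full_evalue,
      hits$bitscore, hits$env_to - hits$env_from + 1L,
      hits$env_from, hits$env_to, hits$env_from, hits$env_to)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a dataset bundle written by [write_dataset()]
#'
#' @param dir directory holding the bundle.
#' @param class_map profile-class map for the hit table.
#' @return a `muf_dataset` (without the generating spec; `spec = NULL`),
#'   including ground truth when the truth tables are present.
#' @export
read_dataset <- function(dir, class_map = default_profile_class_map()) {
  genes <- read_gene_table(file.path(dir, "genes.tsv"))
  hits <- read_domtblout(file.path(dir, "hits.domtblout"), class_map = class_map)
  regions <- read_prophage_regions(file.path(dir, "prophages.tsv"))
  metadata <- utils::read.table(file.path(dir, "metadata.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE, quote = "")
  tg_path <- file.path(dir, "truth_genes.tsv")
  truth_genes <- if (file.exists(tg_path)) {
    utils::read.table(tg_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "")
  } else NULL
  tge_path <- file.path(dir, "truth_genomes.tsv")
  truth_genomes <- if (file.exists(tge_path)) {
    utils::read.table(tge_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "")
  } else NULL
  structure(list(spec = NULL, genes = genes, hits = hits, regions = regions,
                 metadata = metadata, truth_genes = truth_genes,
                 truth_genomes = truth_genomes),
            class = "muf_dataset")
}

# ---- fixtures ---------------------------------------------------------------

#' Small named fixture datasets
#'
#' `"minimal"`: about forty genomes covering every architecture class, both
#' prophage size classes, and a packaging-adjacent muf gene outside any
#' region. `"empty"`: genomes with no muf genes at all (end-to-end runs give
#' all-zero summaries). Fixtures are deterministic across runs.
#'
#' @param name fixture name (`"minimal"` or `"empty"`).
#' @return a `muf_dataset`.
#' @export
make_fixture <- function(name = c("minimal", "empty")) {
  name <- match.arg(name)
  ds <- switch(name,
    minimal = generate_dataset(synthetic_spec(
      seed = 424244L, n_phage_genomes = 24L, n_bacterial_genomes = 20L,
      p_muf_phage = 0.9, p_muf_bacterium = 0.9, p_false_hit = 0,
      architecture_mix = c(SHORT = 0.4, CT_TOXIN = 0.3,
                           CT_UNKNOWN = 0.15, CT_MAD = 0.15),
      assoc_mix = c(IN_PROPHAGE = 0.45, IN_REMNANT = 0.25,
                    NEAR_PACKAGING = 0.2, UNASSOCIATED = 0.1))),
    empty = generate_dataset(synthetic_spec(
      seed = 424243L, n_phage_genomes = 4L, n_bacterial_genomes = 4L,
      p_muf_phage = 0, p_muf_bacterium = 0, p_false_hit = 0))
  )
  if (name == "minimal") {
    stopifnot(all(ARCH_CLASSES %in% ds$truth_genes$architecture),
              all(ASSOC_CLASSES %in% ds$truth_genes$association[
                ds$truth_genes$genome_id %in%
                  ds$metadata$genome_id[ds$metadata$type == "bacterium"]]),
              any(ds$regions$length > 18000L), any(ds$regions$length <= 18000L))
  }
  ds
}
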