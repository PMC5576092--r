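# Association statistics: the exact test and t statistic used throughout the
# analysis, the MuF-family/toxin-domain network, and the summary tables.

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value under the hypergeometric null with fixed margins,
#' using the "probability at most that of the observed table" rule (the
#' convention of R's reference implementation): p is the sum of the
#' probabilities of all tables whose probability does not exceed the observed
#' one (within relative tolerance 1e-7). A zero margin yields p = 1 with a
#' warning.
#'
#' @param a,b,c,d the four cell counts, row-wise (`[[a, b], [c, d]]`).
#' @return the two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_two_tailed(3, 0, 0, 3)   # 0.1
fisher_exact_two_tailed <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers")
  }
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    warning("zero margin: Fisher p set to 1 by convention")
    return(1)
  }
  m <- a + b       # first-row total ("white balls")
  n2 <- c + d      # second-row total
  k <- a + c       # first-column total ("drawn")
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Two-sample unpaired t test statistic
#'
#' Pooled-variance (Student) or Satterthwaite (Welch) two-sample statistic
#' with a two-sided p-value from the t distribution.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @param welch use the Welch statistic (default `TRUE`).
#' @return list with `t`, `df`, `p`, and `method`.
#' @export
two_sample_t <- function(x, y, welch = TRUE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs at least two observations")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) stop("both samples are degenerate (zero variance)")
  dm <- mean(x) - mean(y)
  if (welch) {
    sx <- vx / nx; sy <- vy / ny
    se <- sqrt(sx + sy)
    df <- (sx + sy)^2 / (sx^2 / (nx - 1) + sy^2 / (ny - 1))
    method <- "welch"
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
    method <- "student"
  }
  tstat <- dm / se
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df), method = method)
}

#' MuF-family / toxin-domain association network
#'
#' One weighted edge per (MuF family, toxin domain) pair among `CT_TOXIN`
#' proteins; the weight is the number of proteins carrying that pair. Toxin
#' domains carried by fewer than `min_support` MuF proteins in total are
#' dropped from the network.
#'
#' @param arch architecture-classified MuF table.
#' @param min_support minimal per-domain protein count (default 5).
#' @return data.frame `muf_family`, `toxin_domain`, `weight`.
#' @export
build_network <- function(arch,
                          min_support = default_thresholds()$network_min_support) {
  empty <- data.frame(muf_family = character(), toxin_domain = character(),
                      weight = integer(), stringsAsFactors = FALSE)
  tox <- arch[arch$class == "CT_TOXIN" & nzchar(arch$ct_domains), , drop = FALSE]
  if (!nrow(tox)) return(empty)
  doms <- strsplit(tox$ct_domains, ",", fixed = TRUE)
  pairs <- data.frame(
    muf_family = rep(tox$family, lengths(doms)),
    toxin_domain = unlist(doms),
    protein_id = rep(tox$protein_id, lengths(doms)),
    stringsAsFactors = FALSE
  )
  pairs <- unique(pairs)   # one contribution per (protein, domain)
  support <- table(pairs$toxin_domain)
  keep <- names(support)[support >= min_support]
  pairs <- pairs[pairs$toxin_domain %in% keep, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  agg <- stats::aggregate(list(weight = pairs$protein_id),
                          by = list(muf_family = pairs$muf_family,
                                    toxin_domain = pairs$toxin_domain),
                          FUN = length)
  agg <- agg[order(agg$muf_family, agg$toxin_domain, method = "radix"), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Per-group MuF summary rows
#'
#' For a grouping variable of the genome metadata (`clade`, `phage_family`,
#' `lifestyle`) or the MuF family (`family`), counts genomes, MuF-positive
#' genomes, MuF proteins and their architecture classes, with the
#' corresponding proportions.
#'
#' @param arch architecture-classified MuF table.
#' @param metadata per-genome metadata (`genome_id`, `type`, `clade`,
#'   `phage_family`, `lifestyle`).
#' @param grouping one of `"clade"`, `"phage_family"`, `"lifestyle"`,
#'   `"family"`, `"type"`.
#' @return data.frame of summary rows (one per group level): `grouping`,
#'   `level`, `n_genomes`, `n_muf_pos`, `prop_muf_pos`, `n_muf`, `n_short`,
#'   `n_toxin`, `n_unknown`, `prop_toxin`.
#' @export
summarize_groups <- function(arch, metadata, grouping) {
  genome_keys <- c("clade", "phage_family", "lifestyle", "type")
  if (!grouping %in% c(genome_keys, "family")) {
    stop("unknown grouping key: ", grouping)
  }
  if (grouping == "family") {
    levels_ <- sort(unique(arch$family))
    group_of_protein <- arch$family
    genome_group <- NULL
  } else {
    if (!grouping %in% names(metadata)) {
      stop("metadata lacks column: ", grouping)
    }
    genome_group <- metadata[[grouping]]
    levels_ <- sort(unique(genome_group[!is.na(genome_group)]))
    group_of_protein <- genome_group[match(arch$genome_id, metadata$genome_id)]
  }
  rows <- lapply(levels_, function(lv) {
    in_group <- !is.na(group_of_protein) & group_of_protein == lv
    sub <- arch[in_group, , drop = FALSE]
    if (is.null(genome_group)) {
      n_genomes <- length(unique(sub$genome_id))
      n_pos <- n_genomes
    } else {
      gset <- metadata$genome_id[!is.na(genome_group) & genome_group == lv]
      n_genomes <- length(gset)
      n_pos <- length(unique(sub$genome_id))
    }
    n_muf <- nrow(sub)
    data.frame(
      grouping = grouping, level = lv, n_genomes = n_genomes,
      n_muf_pos = n_pos,
      prop_muf_pos = if (n_genomes) n_pos / n_genomes else NA_real_,
      n_muf = n_muf,
      n_short = sum(sub$class == "SHORT"),
      n_toxin = sum(sub$class == "CT_TOXIN"),
      n_unknown = sum(sub$class == "CT_UNKNOWN"),
      prop_toxin = if (n_muf) sum(sub$class == "CT_TOXIN") / n_muf else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- data.table::setDF(data.table::rbindlist(rows))
  if (!nrow(out)) {
    out <- data.frame(grouping = character(), level = character(),
                      n_genomes = integer(), n_muf_pos = integer(),
                      prop_muf_pos = numeric(), n_muf = integer(),
                      n_short = integer(), n_toxin = integer(),
                      n_unknown = integer(), prop_toxin = numeric(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' The paired association tests of the analysis
#'
#' Reproduces the four 2x2 Fisher comparisons — toxin-vs-short MuF proteins
#' against Firmicutes-vs-other hosts; unknown-extension-vs-short against
#' Proteobacteria-vs-other; muf-positive phage genomes against
#' Siphoviridae-vs-other tailed phages; muf-positive against
#' temperate-vs-virulent phages — plus the t test comparing the lengths of
#' ORFs downstream of toxin vs short muf genes.
#'
#' @param arch architecture-classified MuF table.
#' @param candidates immunity-candidate table ([flag_candidates()]).
#' @param metadata per-genome metadata.
#' @param welch use the Welch t statistic (default) or pooled-variance.
#' @return data.frame with one row per test: `test`, `statistic`, `a`, `b`,
#'   `cc`, `d` (table cells; NA for the t test), `p_value`, `method`.
#' @export
paired_association_tests <- function(arch, candidates, metadata,
                                     welch = TRUE) {
  need <- c("genome_id", "type", "clade", "phage_family", "lifestyle")
  missing_cols <- setdiff(need, names(metadata))
  if (length(missing_cols)) {
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  clade <- metadata$clade[match(arch$genome_id, metadata$genome_id)]

  fisher_row <- function(test, a, b, cc, d) {
    p <- if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) {
      NA_real_
    } else {
      fisher_exact_two_tailed(a, b, cc, d)
    }
    data.frame(test = test, statistic = NA_real_, a = a, b = b, cc = cc,
               d = d, p_value = p, method = "fisher_two_tailed",
               stringsAsFactors = FALSE)
  }

  # 1. toxin-vs-short x Firmicutes-vs-other (MuF proteins)
  sel <- arch$class %in% c("CT_TOXIN", "SHORT")
  firm <- !is.na(clade) & clade == "Firmicutes"
  r1 <- fisher_row("toxin_vs_short_firmicutes",
                   sum(sel & arch$class == "CT_TOXIN" & firm),
                   sum(sel & arch$class == "CT_TOXIN" & !firm),
                   sum(sel & arch$class == "SHORT" & firm),
                   sum(sel & arch$class == "SHORT" & !firm))

  # 2. unknown-extension-vs-short x Proteobacteria-vs-other
  sel <- arch$class %in% c("CT_UNKNOWN", "SHORT")
  prot <- !is.na(clade) & clade == "Proteobacteria"
  r2 <- fisher_row("ctunknown_vs_short_proteobacteria",
                   sum(sel & arch$class == "CT_UNKNOWN" & prot),
                   sum(sel & arch$class == "CT_UNKNOWN" & !prot),
                   sum(sel & arch$class == "SHORT" & prot),
                   sum(sel & arch$class == "SHORT" & !prot))

  # 3. muf x Siphoviridae-vs-other (tailed phage genomes)
  ph <- metadata[metadata$type == "phage" & !is.na(metadata$phage_family) &
                   metadata$phage_family != "NonCaudovirales", , drop = FALSE]
  has_muf <- ph$genome_id %in% arch$genome_id
  sipho <- ph$phage_family == "Siphoviridae"
  r3 <- fisher_row("muf_siphoviridae",
                   sum(has_muf & sipho), sum(has_muf & !sipho),
                   sum(!has_muf & sipho), sum(!has_muf & !sipho))

  # 4. muf x temperate-vs-virulent (labeled phages)
  lab <- metadata[metadata$type == "phage" &
                    metadata$lifestyle %in% c("temperate", "virulent"), ,
                  drop = FALSE]
  has_muf <- lab$genome_id %in% arch$genome_id
  temp <- lab$lifestyle == "temperate"
  r4 <- fisher_row("muf_temperate",
                   sum(has_muf & temp), sum(has_muf & !temp),
                   sum(!has_muf & temp), sum(!has_muf & !temp))

  # 5. downstream-ORF length, toxin vs short (t test)
  lens <- length_distributions(candidates, c("CT_TOXIN", "SHORT"))
  r5 <- if (length(lens$CT_TOXIN) >= 2 && length(lens$SHORT) >= 2) {
    tt <- two_sample_t(lens$CT_TOXIN, lens$SHORT, welch = welch)
    data.frame(test = "downstream_orf_length_toxin_vs_short",
               statistic = tt$t, a = NA_real_, b = NA_real_, cc = NA_real_,
               d = NA_real_, p_value = tt$p,
               method = paste0("t_", tt$method), stringsAsFactors = FALSE)
  } else {
    data.frame(test = "downstream_orf_length_toxin_vs_short",
               statistic = NA_real_, a = NA_real_, b = NA_real_,
               cc = NA_real_, d = NA_real_, p_value = NA_real_,
               method = "t_insufficient_data", stringsAsFactors = FALSE)
  }

  out <- rbind(r1, r2, r3, r4, r5)
  rownames(out) <- NULL
  out
}
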