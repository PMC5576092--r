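# Gene-neighbourhood context of muf genes: signed gene-rank distances to the
# DNA-packaging markers (portal, terminase large/small subunit), prophage
# association categories and lysogeny.

#' Signed gene-rank distances from a muf gene to the nearest marker genes
#'
#' For each marker class, returns the signed offset `marker_rank - muf_rank`
#' of minimal absolute value within `window` genes on either side; ties
#' between `-k` and `+k` resolve to `+k`; `NA` when no marker lies within
#' the window.
#'
#' @param muf_rank gene rank of the muf gene on its replicon.
#' @param marker_ranks named list of integer rank vectors, one per marker
#'   class (e.g. `list(PORTAL = ..., TLS = ..., TSS = ...)`).
#' @param n_genes number of genes on the replicon (for rank validation).
#' @param window window half-width in genes (default 10).
#' @return named integer vector of signed distances (NA = none in window).
#' @export
#' @examples
#' marker_distances(10, list(PORTAL = 11L), n_genes = 20)  # PORTAL = +1
marker_distances <- function(muf_rank, marker_ranks, n_genes,
                             window = default_thresholds()$context_window) {
  if (muf_rank < 0L || muf_rank >= n_genes) {
    stop("muf_rank ", muf_rank, " out of range for a replicon of ",
         n_genes, " genes")
  }
  vapply(marker_ranks, function(ranks) {
    ranks <- ranks[ranks != muf_rank]
    if (!length(ranks)) return(NA_integer_)
    d <- as.integer(ranks - muf_rank)
    d <- d[abs(d) <= window]
    if (!length(d)) return(NA_integer_)
    # minimal |d|; ties between -k and +k resolve to +k
    d[order(abs(d), -sign(d), method = "radix")][[1]]
  }, integer(1))
}

#' Identify packaging-marker genes from the hit table
#'
#' A gene is a marker gene when its protein's best-e-value hit among the
#' marker classes (PORTAL/TLS/TSS) belongs to that class.
#'
#' @param hits domain-hit table.
#' @param genes gene table.
#' @return data.frame `gene_id`, `genome_id`, `replicon_id`, `rank`,
#'   `marker_class`.
#' @export
marker_genes <- function(hits, genes) {
  mh <- hits[hits$passed_ga & hits$profile_class %in% MARKER_CLASSES, ,
             drop = FALSE]
  mh <- mh[mh$protein_id %in% genes$gene_id, , drop = FALSE]
  if (!nrow(mh)) {
    return(data.frame(gene_id = character(), genome_id = character(),
                      replicon_id = character(), rank = integer(),
                      marker_class = character(), stringsAsFactors = FALSE))
  }
  ord <- order(mh$protein_id, mh$full_evalue, -mh$bitscore, mh$profile_name,
               method = "radix")
  mh <- mh[ord, , drop = FALSE]
  best <- mh[!duplicated(mh$protein_id), , drop = FALSE]
  gi <- match(best$protein_id, genes$gene_id)
  data.frame(gene_id = best$protein_id,
             genome_id = genes$genome_id[gi],
             replicon_id = genes$replicon_id[gi],
             rank = genes$rank[gi],
             marker_class = best$profile_class,
             stringsAsFactors = FALSE)
}

#' Prophage-association category of one muf gene
#'
#' A gene whose midpoint lies within a region longer than `prophage_min`
#' (default 18 kb) is `IN_PROPHAGE`; within a region of at most that length,
#' `IN_REMNANT` (the largest containing region wins when regions of both
#' size classes contain the gene, with a warning); otherwise
#' `NEAR_PACKAGING` when any marker distance is defined within the context
#' window; otherwise `UNASSOCIATED`.
#'
#' @param gene_start,gene_end internal 0-based half-open gene coordinates.
#' @param regions prophage regions on the gene's replicon (`start`, `end`,
#'   `length`).
#' @param any_marker_near `TRUE` when a portal/terminase gene lies within the
#'   context window.
#' @param thresholds a [default_thresholds()] list.
#' @return one of `"IN_PROPHAGE"`, `"IN_REMNANT"`, `"NEAR_PACKAGING"`,
#'   `"UNASSOCIATED"`.
#' @export
assign_association <- function(gene_start, gene_end, regions,
                               any_marker_near,
                               thresholds = default_thresholds()) {
  mid <- (gene_start + gene_end) / 2
  containing <- regions[regions$start <= mid & mid < regions$end, , drop = FALSE]
  if (nrow(containing)) {
    big <- containing$length > thresholds$prophage_min
    if (any(big) && any(!big)) {
      warning("gene contained in overlapping prophage and remnant regions; ",
              "largest region wins")
    }
    best <- which.max(containing$length)
    return(if (containing$length[[best]] > thresholds$prophage_min)
      "IN_PROPHAGE" else "IN_REMNANT")
  }
  if (isTRUE(any_marker_near)) "NEAR_PACKAGING" else "UNASSOCIATED"
}

#' Is a genome a lysogen?
#'
#' A genome is lysogenic when it carries at least one prophage region longer
#' than the prophage cutoff (default 18 kb).
#'
#' @param regions prophage regions of one genome.
#' @param thresholds a [default_thresholds()] list.
#' @return logical.
#' @export
classify_lysogen <- function(regions, thresholds = default_thresholds()) {
  nrow(regions) > 0 && any(regions$length > thresholds$prophage_min)
}

#' Genomic-context profiles of all muf genes
#'
#' Computes, for every MuF call, the signed gene-rank distances to the
#' nearest portal/TLS/TSS genes within the context window, and (for
#' bacterial genes) the prophage-association category. Phage genes get
#' `association = NA` (not applicable). `portal_offset_of_muf` is the muf
#' gene's rank offset from the nearest portal gene (`-d_portal`), the
#' orientation in which packaging modules are usually described (muf at +1
#' of the portal gene).
#'
#' @param muf_calls MuF protein table.
#' @param genes gene table.
#' @param hits domain-hit table (for marker genes).
#' @param regions prophage region table.
#' @param metadata per-genome metadata with a `type` column
#'   (`"phage"`/`"bacterium"`).
#' @param thresholds a [default_thresholds()] list.
#' @return data.frame: `gene_id`, `genome_id`, `d_portal`, `d_tls`, `d_tss`,
#'   `portal_offset_of_muf`, `near_packaging`, `association`.
#' @export
context_profiles <- function(muf_calls, genes, hits, regions, metadata,
                             thresholds = default_thresholds()) {
  markers <- marker_genes(hits, genes)
  n <- nrow(muf_calls)
  out <- data.frame(
    gene_id = muf_calls$gene_id, genome_id = muf_calls$genome_id,
    d_portal = rep(NA_integer_, n), d_tls = rep(NA_integer_, n),
    d_tss = rep(NA_integer_, n), portal_offset_of_muf = rep(NA_integer_, n),
    near_packaging = rep(FALSE, n),
    association = rep(NA_character_, n), stringsAsFactors = FALSE
  )
  if (!n) return(out)
  gi <- match(muf_calls$gene_id, genes$gene_id)
  repl <- genes$replicon_id[gi]
  n_genes_repl <- table(genes$replicon_id)
  type <- metadata$type[match(muf_calls$genome_id, metadata$genome_id)]

  for (i in seq_len(nrow(out))) {
    mrk <- markers[markers$replicon_id == repl[[i]], , drop = FALSE]
    mr <- list(PORTAL = mrk$rank[mrk$marker_class == "PORTAL"],
               TLS = mrk$rank[mrk$marker_class == "TLS"],
               TSS = mrk$rank[mrk$marker_class == "TSS"])
    d <- marker_distances(genes$rank[gi[[i]]], mr,
                          n_genes = as.integer(n_genes_repl[[repl[[i]]]]),
                          window = thresholds$context_window)
    out$d_portal[[i]] <- d[["PORTAL"]]
    out$d_tls[[i]] <- d[["TLS"]]
    out$d_tss[[i]] <- d[["TSS"]]
    out$portal_offset_of_muf[[i]] <- -d[["PORTAL"]]
    out$near_packaging[[i]] <- any(!is.na(d))
    if (identical(type[[i]], "bacterium")) {
      reg <- regions[regions$replicon_id == repl[[i]], , drop = FALSE]
      out$association[[i]] <- assign_association(
        genes$start[gi[[i]]], genes$end[gi[[i]]], reg,
        out$near_packaging[[i]], thresholds)
    }
  }
  out
}

#' Lysogeny table for all genomes
#'
#' @param metadata per-genome metadata (`genome_id`, `type`).
#' @param regions prophage region table.
#' @param thresholds a [default_thresholds()] list.
#' @return data.frame `genome_id`, `type`, `lysogen` (NA for phages).
#' @export
lysogeny_table <- function(metadata, regions,
                           thresholds = default_thresholds()) {
  lys <- vapply(metadata$genome_id, function(g) {
    classify_lysogen(regions[regions$genome_id == g, , drop = FALSE],
                     thresholds)
  }, logical(1))
  data.frame(genome_id = metadata$genome_id, type = metadata$type,
             lysogen = ifelse(metadata$type == "bacterium", lys, NA),
             stringsAsFactors = FALSE)
}
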