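# Candidate immunity ORFs: the gene immediately downstream of each muf gene
# in its transcription orientation, flagged as small when it encodes < 150 aa.

#' The gene immediately downstream of a gene, in transcription orientation
#'
#' For a gene on the `+` strand this is the gene at `rank + 1`; on the `-`
#' strand, `rank - 1`. Returns `NULL` at replicon ends.
#'
#' @param genes gene table (all replicons allowed; the query gene's replicon
#'   is used).
#' @param gene one-row data.frame (a row of the gene table).
#' @return a one-row data.frame, or `NULL`.
#' @export
downstream_gene <- function(genes, gene) {
  target_rank <- if (gene$strand == "+") gene$rank + 1L else gene$rank - 1L
  hit <- genes[genes$genome_id == gene$genome_id &
                 genes$replicon_id == gene$replicon_id &
                 genes$rank == target_rank, , drop = FALSE]
  if (nrow(hit)) hit else NULL
}

#' Flag small-ORF immunity candidates downstream of muf genes
#'
#' One record per MuF protein: the immediately downstream gene (if any), its
#' protein length, whether it is co-oriented with the muf gene, the
#' intergenic gap in bp, and the small-ORF flag (`downstream length` strictly
#' below the small-ORF cutoff, default 150 aa). Co-orientation and gap are
#' reported, not required.
#'
#' @param muf_arch architecture-classified MuF table
#'   ([classify_architecture()] output).
#' @param genes gene table.
#' @param thresholds a [default_thresholds()] list.
#' @return data.frame: `muf_gene_id`, `genome_id`, `class`, `ctmad`,
#'   `downstream_gene_id`, `downstream_aa_length`, `co_oriented`, `gap_bp`,
#'   `is_small`.
#' @export
flag_candidates <- function(muf_arch, genes,
                            thresholds = default_thresholds()) {
  n <- nrow(muf_arch)
  out <- data.frame(
    muf_gene_id = muf_arch$gene_id, genome_id = muf_arch$genome_id,
    class = if (n) muf_arch$class else character(0),
    ctmad = if (n) muf_arch$ctmad else logical(0),
    downstream_gene_id = rep(NA_character_, n),
    downstream_aa_length = rep(NA_integer_, n),
    co_oriented = rep(NA, n), gap_bp = rep(NA_integer_, n),
    is_small = rep(FALSE, n), stringsAsFactors = FALSE
  )
  if (!n) return(out)
  gi <- match(muf_arch$gene_id, genes$gene_id)
  for (i in seq_len(n)) {
    g <- genes[gi[[i]], , drop = FALSE]
    ds <- downstream_gene(genes, g)
    if (is.null(ds)) next
    out$downstream_gene_id[[i]] <- ds$gene_id
    out$downstream_aa_length[[i]] <- ds$aa_length
    out$co_oriented[[i]] <- ds$strand == g$strand
    out$gap_bp[[i]] <- if (g$strand == "+") ds$start - g$end else g$start - ds$end
    out$is_small[[i]] <- ds$aa_length < thresholds$small_orf_max
  }
  out
}

#' Downstream-ORF length samples per architecture class
#'
#' Splits the downstream protein lengths of the immunity-candidate table by
#' architecture class; records without a downstream gene are excluded.
#'
#' @param candidates [flag_candidates()] output.
#' @param classes classes to report (default all three).
#' @return named list of integer vectors.
#' @export
length_distributions <- function(candidates,
                                 classes = c("CT_TOXIN", "CT_UNKNOWN", "SHORT")) {
  out <- lapply(classes, function(cl) {
    x <- candidates$downstream_aa_length[candidates$class == cl]
    x <- x[!is.na(x)]
    if (!length(x)) {
      warning("no downstream-length observations for class ", cl)
    }
    as.integer(x)
  })
  names(out) <- classes
  out
}
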