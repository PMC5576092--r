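# MuF protein calling: one protein, one family, from its best-e-value
# MuF-class profile hit.

#' Select the best-e-value profile hit for one protein
#'
#' Among the hits of a single protein (optionally restricted to a set of
#' profile classes), returns the hit with the smallest full-sequence E-value.
#' Ties are broken by higher bitscore, then by lexicographic profile name.
#'
#' @param hits domain-hit data.frame for one protein.
#' @param classes optional character vector of profile classes to consider.
#' @return a one-row data.frame, or `NULL` when no hit qualifies.
#' @export
select_best_profile <- function(hits, classes = NULL) {
  if (!nrow(hits)) return(NULL)
  if (length(unique(hits$protein_id)) > 1L) {
    stop("select_best_profile expects hits of a single protein; got: ",
         paste(unique(hits$protein_id), collapse = ", "))
  }
  if (!is.null(classes)) {
    hits <- hits[hits$profile_class %in% classes, , drop = FALSE]
  }
  if (!nrow(hits)) return(NULL)
  ord <- order(hits$full_evalue, -hits$bitscore, hits$profile_name,
               method = "radix")
  hits[ord[[1]], , drop = FALSE]
}

#' Call MuF proteins from a domain-hit table
#'
#' Every protein with at least one GA-passing MuF-class hit (MUF1..MUF4)
#' becomes one MuF protein; its family and domain envelope are taken from the
#' best-e-value MuF hit ([select_best_profile()]). Protein identifiers are
#' the gene identifiers of the annotation table; a MuF hit on a protein
#' absent from the gene table is an error.
#'
#' @param hits domain-hit data.frame ([read_domtblout()] layout).
#' @param genes gene data.frame ([read_gene_table()] layout).
#' @return data.frame with one row per MuF protein: `protein_id`,
#'   `genome_id`, `gene_id`, `family`, `muf_env_from`, `muf_env_to`,
#'   `aa_length`, `best_evalue`.
#' @export
call_muf_proteins <- function(hits, genes) {
  muf_hits <- hits[hits$passed_ga & hits$profile_class %in% MUF_CLASSES, ,
                   drop = FALSE]
  if (!nrow(muf_hits)) {
    return(data.frame(protein_id = character(), genome_id = character(),
                      gene_id = character(), family = character(),
                      muf_env_from = integer(), muf_env_to = integer(),
                      aa_length = integer(), best_evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  orphans <- setdiff(unique(muf_hits$protein_id), genes$gene_id)
  if (length(orphans)) {
    stop("MuF hits on proteins absent from the gene table: ",
         paste(utils::head(orphans, 5), collapse = ", "))
  }
  # best MuF-class hit per protein: order globally, keep first per protein
  ord <- order(muf_hits$protein_id, muf_hits$full_evalue, -muf_hits$bitscore,
               muf_hits$profile_name, method = "radix")
  muf_hits <- muf_hits[ord, , drop = FALSE]
  best <- muf_hits[!duplicated(muf_hits$protein_id), , drop = FALSE]
  gi <- match(best$protein_id, genes$gene_id)
  calls <- data.frame(
    protein_id = best$protein_id,
    genome_id = genes$genome_id[gi],
    gene_id = best$protein_id,
    family = best$profile_class,
    muf_env_from = best$env_from,
    muf_env_to = best$env_to,
    aa_length = genes$aa_length[gi],
    best_evalue = best$full_evalue,
    stringsAsFactors = FALSE
  )
  bad <- calls$muf_env_to > calls$aa_length
  if (any(bad)) {
    # an envelope beyond the annotated protein length indicates inconsistent
    # inputs; clamp and keep (spurious hits on short proteins do this)
    calls$muf_env_to[bad] <- calls$aa_length[bad]
    calls$muf_env_from[bad] <- pmin(calls$muf_env_from[bad], calls$aa_length[bad])
  }
  ord <- order(calls$genome_id, calls$gene_id, method = "radix")
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  calls
}
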