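# C-terminal architecture of MuF proteins: short, toxin extension, or
# unknown extension (with Ct_MAD subtype).

#' C-terminal extension length of a MuF protein
#'
#' The extension is measured from the end of the MuF domain envelope to the
#' protein's C-terminus; an extension of `ct_extension_min` (default 100) or
#' more amino acids counts as present.
#'
#' @param aa_length protein length (aa).
#' @param muf_env_to MuF envelope end (aa, 1-based inclusive).
#' @return integer vector of extension lengths.
#' @export
#' @examples
#' ct_extension_length(300, 150)  # 150
ct_extension_length <- function(aa_length, muf_env_to) {
  if (any(muf_env_to > aa_length)) {
    stop("muf_env_to exceeds protein length")
  }
  as.integer(aa_length - muf_env_to)
}

#' Classify the C-terminal architecture of MuF proteins
#'
#' Each MuF protein is `SHORT` when its C-terminal extension is below the
#' cutoff; `CT_TOXIN` when a catalog toxin domain's envelope midpoint lies
#' within the extension; otherwise `CT_UNKNOWN`, with `ctmad = TRUE` when a
#' Ct_MAD hit lies in the extension. Toxin hits N-terminal of the MuF domain
#' are reported in `ct_domains` context but never class-determining: the
#' classes are defined on the C-terminal region only.
#'
#' @param muf_calls MuF protein table from [call_muf_proteins()].
#' @param hits full domain-hit table (the non-MuF hits of each protein are
#'   used).
#' @param toxin_catalog character vector of toxin-domain names (default:
#'   bundled catalog).
#' @param thresholds a [default_thresholds()] list.
#' @return `muf_calls` with added columns `ct_length`, `has_extension`,
#'   `class`, `ct_domains` (comma-joined names in the extension), `ctmad`.
#' @export
classify_architecture <- function(muf_calls, hits,
                                  toxin_catalog = default_toxin_catalog()$name,
                                  thresholds = default_thresholds()) {
  n <- nrow(muf_calls)
  muf_calls$ct_length <- if (n) {
    ct_extension_length(muf_calls$aa_length, muf_calls$muf_env_to)
  } else integer(0)
  muf_calls$has_extension <- muf_calls$ct_length >= thresholds$ct_extension_min
  muf_calls$class <- ifelse(muf_calls$has_extension, "CT_UNKNOWN", "SHORT")
  muf_calls$ct_domains <- character(n)
  muf_calls$ctmad <- logical(n)
  if (!n) return(muf_calls)

  other <- hits[hits$passed_ga & !hits$profile_class %in% MUF_CLASSES, ,
                drop = FALSE]
  other <- other[other$protein_id %in% muf_calls$protein_id, , drop = FALSE]
  if (nrow(other)) {
    idx <- match(other$protein_id, muf_calls$protein_id)
    midpoint <- (other$env_from + other$env_to) / 2
    in_ext <- muf_calls$has_extension[idx] &
      midpoint > muf_calls$muf_env_to[idx]
    is_toxin <- other$profile_name %in% toxin_catalog
    is_ctmad <- other$profile_class == "CT_MAD"

    tox_idx <- idx[in_ext & is_toxin]
    if (length(tox_idx)) {
      muf_calls$class[unique(tox_idx)] <- "CT_TOXIN"
      doms <- tapply(other$profile_name[in_ext & is_toxin], tox_idx,
                     function(x) paste(sort(unique(x)), collapse = ","))
      muf_calls$ct_domains[as.integer(names(doms))] <- unname(doms)
    }
    mad_idx <- unique(idx[in_ext & is_ctmad])
    muf_calls$ctmad[mad_idx] <- TRUE
  }
  muf_calls
}
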