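#' Pipeline thresholds
#'
#' Every numeric cutoff used by the pipeline lives here, so that a single
#' object documents (and lets the user vary) the operating point:
#'
#' * `ct_extension_min` (aa): minimal C-terminal extension length, inclusive
#'   (an extension of exactly 100 aa counts as an extension).
#' * `small_orf_max` (aa): strict upper bound for a "small ORF" immunity
#'   candidate (a 150-aa product is *not* small).
#' * `prophage_min` (bp): strict lower bound for a complete prophage; regions
#'   of exactly this length are remnants.
#' * `context_window` (genes): half-width of the gene-rank window used both
#'   for marker distances and for the "near packaging genes" remnant rule.
#' * `network_min_support` (proteins): minimal number of MuF proteins
#'   carrying a toxin domain for that domain to enter the association network.
#'
#' @param ct_extension_min minimal extension length in amino acids.
#' @param small_orf_max small-ORF cutoff in amino acids (strict `<`).
#' @param prophage_min prophage length cutoff in bp (strict `>`).
#' @param context_window gene-rank window half-width.
#' @param network_min_support minimal per-toxin-domain protein count.
#' @return A named list of class `muf_thresholds`.
#' @export
#' @examples
#' default_thresholds()
default_thresholds <- function(ct_extension_min = 100L,
                               small_orf_max = 150L,
                               prophage_min = 18000L,
                               context_window = 10L,
                               network_min_support = 5L) {
  th <- list(
    ct_extension_min = as.integer(ct_extension_min),
    small_orf_max = as.integer(small_orf_max),
    prophage_min = as.integer(prophage_min),
    context_window = as.integer(context_window),
    network_min_support = as.integer(network_min_support)
  )
  bad <- names(th)[!vapply(th, function(x) length(x) == 1L && !is.na(x) && x > 0L, logical(1))]
  if (length(bad)) {
    stop("thresholds must be single positive integers: ", paste(bad, collapse = ", "))
  }
  class(th) <- "muf_thresholds"
  th
}
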