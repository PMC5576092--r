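#' Profile classes recognised by the pipeline
#'
#' Domain hits are grouped into functional classes: the four MuF family
#' profiles, the Ct_MAD C-terminal domain, the DNA-packaging markers
#' (portal, terminase large/small subunit), catalog toxin domains, and
#' everything else (`OTHER`).
#'
#' @return Character vector of the class labels.
#' @export
profile_classes <- function() {
  c("MUF1", "MUF2", "MUF3", "MUF4", "CT_MAD",
    "PORTAL", "TLS", "TSS", "TOXIN", "OTHER")
}

MUF_CLASSES <- c("MUF1", "MUF2", "MUF3", "MUF4")
MARKER_CLASSES <- c("PORTAL", "TLS", "TSS")

#' Default profile-name to class map
#'
#' Maps HMM profile names to pipeline classes. MuF1 and MuF2 correspond to
#' the Pfam families Phage_Mu_F (PF04233) and Phage_min_cap2 (PF06152);
#' MuF3, MuF4 and Ct_MAD are context-defined profiles. Packaging markers
#' cover the common portal and terminase profile names. Names listed in the
#' toxin catalog are mapped to `TOXIN`; any unknown profile maps to `OTHER`
#' at parse time.
#'
#' @param toxin_catalog optional character vector of toxin-domain profile
#'   names to map to class `TOXIN` (default: [default_toxin_catalog()]).
#' @return data.frame with columns `profile_name`, `profile_class`.
#' @export
default_profile_class_map <- function(toxin_catalog = default_toxin_catalog()$name) {
  base <- data.frame(
    profile_name = c(
      "MuF1", "PF04233", "Phage_Mu_F",
      "MuF2", "PF06152", "Phage_min_cap2",
      "MuF3", "MuF4",
      "Ct_MAD",
      "Phage_portal", "Portal", "TIGR01539",
      "Terminase_GpA", "Terminase_1", "Terminase_6", "TIGR01547",
      "Terminase_2", "Terminase_4", "Phage_term_smal"
    ),
    profile_class = c(
      "MUF1", "MUF1", "MUF1",
      "MUF2", "MUF2", "MUF2",
      "MUF3", "MUF4",
      "CT_MAD",
      "PORTAL", "PORTAL", "PORTAL",
      "TLS", "TLS", "TLS", "TLS",
      "TSS", "TSS", "TSS"
    ),
    stringsAsFactors = FALSE
  )
  if (length(toxin_catalog)) {
    base <- rbind(base, data.frame(profile_name = toxin_catalog,
                                   profile_class = "TOXIN",
                                   stringsAsFactors = FALSE))
  }
  base[!duplicated(base$profile_name), , drop = FALSE]
}

#' Read a toxin-domain catalog table
#'
#' The catalog is a two-column TSV (`name`, `activity`) naming the C-terminal
#' toxin-domain families that define the `CT_TOXIN` architecture. Duplicate
#' rows with a consistent activity are deduplicated; duplicate names with
#' conflicting activities are an error.
#'
#' @param path path to the TSV (header `name<TAB>activity`).
#' @return data.frame with columns `name`, `activity`.
#' @export
toxin_catalog_from_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  if (!all(c("name", "activity") %in% names(tab))) {
    stop("toxin catalog must have columns 'name' and 'activity'")
  }
  tab <- unique(tab[, c("name", "activity")])
  dup <- tab$name[duplicated(tab$name)]
  if (length(dup)) {
    stop("conflicting activity classes for toxin domain(s): ",
         paste(unique(dup), collapse = ", "))
  }
  rownames(tab) <- NULL
  tab
}

#' Default toxin-domain catalog
#'
#' Bundled catalog of the toxin-domain families most often fused to MuF
#' C-terminal extensions (nucleases such as Ntox50 and EndoU_bacteria, the
#' cd13442 tRNase, ADP-ribosyl transferases, RelA-like and metallopeptidase
#' domains). Users mining real hit tables should supply their own, larger
#' catalog via [toxin_catalog_from_table()].
#'
#' @return data.frame with columns `name`, `activity`.
#' @export
default_toxin_catalog <- function() {
  path <- system.file("extdata", "toxin_domains.tsv", package = "mufscan")
  if (nzchar(path)) {
    return(toxin_catalog_from_table(path))
  }
  # fallback during development when the package is not installed
  data.frame(
    name = c("Ntox50", "EndoU_bacteria", "cd13442", "Ntox34",
             "ADPRT_tox", "RelA_SpoT_tox", "Peptidase_M35_tox", "Colicin_D"),
    activity = c("nuclease", "ribonuclease", "tRNase", "nuclease",
                 "ADP-ribosyl transferase", "ppGpp synthetase",
                 "metallopeptidase", "ribonuclease"),
    stringsAsFactors = FALSE
  )
}
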