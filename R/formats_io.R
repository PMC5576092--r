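#' @importFrom data.table rbindlist setDF
NULL

# ---- coordinate conventions -------------------------------------------------
#
# All coordinates inside the package are 0-based half-open [start, end).
# Annotation tables and GFF3 are 1-based inclusive; the two helpers below are
# the single conversion site.

#' Convert 1-based inclusive coordinates to internal 0-based half-open
#'
#' @param start,end 1-based inclusive coordinates (`start <= end`).
#' @return list with elements `start`, `end` in 0-based half-open convention.
#' @export
#' @examples
#' coords_to_internal(1, 300)   # $start 0, $end 300
coords_to_internal <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L) || any(end < start)) {
    stop("1-based inclusive coordinates require 1 <= start <= end")
  }
  list(start = start - 1L, end = end)
}

#' Convert internal 0-based half-open coordinates back to 1-based inclusive
#'
#' Exact inverse of [coords_to_internal()].
#' @param start,end 0-based half-open coordinates (`start < end`).
#' @return list with elements `start`, `end` in 1-based inclusive convention.
#' @export
coords_to_onebased <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L) || any(end <= start)) {
    stop("0-based half-open coordinates require 0 <= start < end")
  }
  list(start = start + 1L, end = end)
}

# ---- gene tables ------------------------------------------------------------

GENE_COLUMNS <- c("gene_id", "genome_id", "replicon_id", "start", "end",
                  "strand", "rank", "aa_length", "product_label")

#' Assign per-replicon gene ranks by coordinate order
#'
#' Rank is the 0-based position of a gene in its replicon's gene order
#' (sorted by start, ties by end then gene_id), strand-agnostic.
#'
#' @param genes gene data.frame with internal coordinates.
#' @return the data.frame sorted by (genome, replicon, start) with a `rank`
#'   column.
#' @keywords internal
assign_ranks <- function(genes) {
  ord <- order(genes$genome_id, genes$replicon_id, genes$start, genes$end,
               genes$gene_id, method = "radix")
  genes <- genes[ord, , drop = FALSE]
  key <- paste(genes$genome_id, genes$replicon_id, sep = "\r")
  genes$rank <- stats::ave(seq_along(key), key, FUN = seq_along) - 1L
  rownames(genes) <- NULL
  genes
}

#' Read a gene annotation table
#'
#' Reads per-genome CDS annotations in either the pipeline's tabular dialect
#' (TSV with header; columns `gene_id`, `genome_id`, `replicon_id`, `start`,
#' `end`, `strand`, optional `aa_length` and `product_label`; 1-based
#' inclusive coordinates) or GFF3 (CDS features; requires the rtracklayer
#' package). Coordinates are converted to the internal 0-based half-open
#' convention, genes are sorted by start within each replicon and assigned a
#' 0-based `rank`, and protein length is taken from `aa_length` when present,
#' otherwise derived as `(span / 3) - 1` for a stop-inclusive CDS.
#'
#' @param path path to the annotation file.
#' @param dialect `"tsv"` (default) or `"gff3"`.
#' @param genome_id genome identifier to assign when the file does not carry
#'   one (GFF3; defaults to the file name without extension).
#' @return data.frame of gene records (one row per CDS) with columns
#'   `r paste(GENE_COLUMNS, collapse = ", ")`.
#' @export
read_gene_table <- function(path, dialect = c("tsv", "gff3"),
                            genome_id = NULL) {
  dialect <- match.arg(dialect)
  genes <- switch(dialect,
                  tsv = read_gene_tsv(path),
                  gff3 = read_gene_gff3(path, genome_id))
  validate_gene_table(genes)
}

read_gene_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(empty_gene_table())
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  required <- c("gene_id", "genome_id", "replicon_id", "start", "end", "strand")
  if (!all(required %in% header)) {
    stop("gene table header must contain: ", paste(required, collapse = ", "))
  }
  ncol_expected <- length(header)
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  bad <- which(nfield != ncol_expected)
  if (length(bad)) {
    stop("malformed gene table line ", bad[[1]] + 1L, ": expected ",
         ncol_expected, " fields, found ", nfield[[bad[[1]]]])
  }
  if (!length(fields)) {
    return(empty_gene_table())
  }
  mat <- matrix(unlist(fields), ncol = ncol_expected, byrow = TRUE)
  colnames(mat) <- header
  tab <- as.data.frame(mat, stringsAsFactors = FALSE)
  start1 <- suppressWarnings(as.integer(tab$start))
  end1 <- suppressWarnings(as.integer(tab$end))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad)) {
    stop("malformed gene table line ", bad[[1]] + 1L,
         ": non-integer coordinates")
  }
  cc <- coords_to_internal(start1, end1)
  aa <- if ("aa_length" %in% names(tab)) {
    suppressWarnings(as.integer(tab$aa_length))
  } else {
    rep(NA_integer_, nrow(tab))
  }
  data.frame(
    gene_id = tab$gene_id,
    genome_id = tab$genome_id,
    replicon_id = tab$replicon_id,
    start = cc$start,
    end = cc$end,
    strand = tab$strand,
    aa_length = aa,
    product_label = if ("product_label" %in% names(tab)) tab$product_label else "",
    stringsAsFactors = FALSE
  )
}

read_gene_gff3 <- function(path, genome_id = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the 'rtracklayer' package")
  }
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  }
  g <- as.data.frame(rtracklayer::readGFF(path, filter = list(type = "CDS")))
  if (!nrow(g)) {
    return(empty_gene_table())
  }
  ids <- if ("ID" %in% names(g) && !all(is.na(g$ID))) g$ID else g$seqid
  ids <- as.character(ids)
  ids[is.na(ids) | !nzchar(ids)] <- paste0("cds_", which(is.na(ids) | !nzchar(ids)))
  cc <- coords_to_internal(g$start, g$end)
  data.frame(
    gene_id = ids,
    genome_id = genome_id,
    replicon_id = as.character(g$seqid),
    start = cc$start,
    end = cc$end,
    strand = as.character(g$strand),
    aa_length = NA_integer_,
    product_label = if ("product" %in% names(g)) as.character(g$product) else "",
    stringsAsFactors = FALSE
  )
}

empty_gene_table <- function() {
  data.frame(gene_id = character(), genome_id = character(),
             replicon_id = character(), start = integer(), end = integer(),
             strand = character(), rank = integer(), aa_length = integer(),
             product_label = character(), stringsAsFactors = FALSE)
}

validate_gene_table <- function(genes) {
  if (!nrow(genes)) {
    return(empty_gene_table())
  }
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  key <- paste(genes$genome_id, genes$replicon_id, genes$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- genes$gene_id[duplicated(key)]
    stop("duplicate gene_id within a replicon: ",
         paste(unique(dup), collapse = ", "))
  }
  # derive protein length from the CDS span (stop codon excluded) when absent
  span <- genes$end - genes$start
  derived <- as.integer(span %/% 3L - 1L)
  genes$aa_length <- ifelse(is.na(genes$aa_length), derived, genes$aa_length)
  if (any(genes$aa_length < 1L)) {
    stop("aa_length must be >= 1 (offending gene(s): ",
         paste(utils::head(genes$gene_id[genes$aa_length < 1L], 3), collapse = ", "), ")")
  }
  genes <- assign_ranks(genes)
  genes[, GENE_COLUMNS]
}

# ---- HMMER3 domtblout -------------------------------------------------------

DOMHIT_COLUMNS <- c("protein_id", "profile_name", "profile_class",
                    "full_evalue", "bitscore", "env_from", "env_to",
                    "passed_ga")

#' Read an HMMER3 per-domain hit table (domtblout)
#'
#' Parses the 23+-column whitespace-separated per-domain table written by
#' `hmmsearch --domtblout`. One hit is produced per domain line, keeping the
#' target (protein) name, query (profile) name, full-sequence E-value,
#' bitscore and envelope coordinates. Hits present in the file are assumed to
#' have passed the profile's GA gathering threshold (the scan is expected to
#' have been run with `--cut_ga`) unless `raw = TRUE`, in which case
#' `passed_ga` is set to `FALSE` for every hit and downstream screening must
#' apply its own threshold.
#'
#' @param path path to the domtblout file.
#' @param class_map data.frame (`profile_name`, `profile_class`) mapping
#'   profile names to pipeline classes; unmapped profiles become `OTHER`.
#' @param raw set `TRUE` for an unfiltered scan (marks `passed_ga = FALSE`).
#' @return data.frame of domain hits with columns
#'   `r paste(DOMHIT_COLUMNS, collapse = ", ")`.
#' @export
read_domtblout <- function(path, class_map = default_profile_class_map(),
                           raw = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) {
    return(empty_domhit_table())
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nfield <- lengths(fields)
  bad <- which(nfield < 23L)
  if (length(bad)) {
    stop("malformed domtblout line ", which(keep)[bad[[1]]],
         ": expected >= 23 columns, found ", nfield[[bad[[1]]]])
  }
  # domtblout column layout (1-based): 1 target, 4 query, 7 full E-value,
  # 8 full score, 20 env from, 21 env to
  col <- function(i) vapply(fields, `[[`, character(1), i)
  hits <- data.frame(
    protein_id = col(1L),
    profile_name = col(4L),
    full_evalue = as.numeric(col(7L)),
    bitscore = as.numeric(col(8L)),
    env_from = as.integer(col(20L)),
    env_to = as.integer(col(21L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(hits$full_evalue) || anyNA(hits$env_from) || anyNA(hits$env_to)) {
    stop("malformed domtblout: non-numeric E-value or envelope column")
  }
  if (any(hits$full_evalue < 0)) {
    stop("negative E-value in domtblout")
  }
  if (any(hits$env_from < 1L) || any(hits$env_to < hits$env_from)) {
    stop("invalid envelope coordinates in domtblout (need 1 <= from <= to)")
  }
  hits$profile_class <- classify_profiles(hits$profile_name, class_map)
  hits$passed_ga <- !raw
  hits[, DOMHIT_COLUMNS]
}

classify_profiles <- function(profile_name, class_map) {
  cls <- class_map$profile_class[match(profile_name, class_map$profile_name)]
  cls[is.na(cls)] <- "OTHER"
  cls
}

empty_domhit_table <- function() {
  data.frame(protein_id = character(), profile_name = character(),
             profile_class = character(), full_evalue = numeric(),
             bitscore = numeric(), env_from = integer(), env_to = integer(),
             passed_ga = logical(), stringsAsFactors = FALSE)
}

# ---- prophage regions -------------------------------------------------------

#' Read a prophage region table
#'
#' BED-like TSV with header columns `genome_id`, `replicon_id`, `start`,
#' `end` in 0-based half-open coordinates, as produced by an external
#' prophage detector. A `length` column is computed as `end - start`.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `genome_id`, `replicon_id`, `start`,
#'   `end`, `length`.
#' @export
read_prophage_regions <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  required <- c("genome_id", "replicon_id", "start", "end")
  if (!all(required %in% names(tab))) {
    stop("prophage region table must have columns: ",
         paste(required, collapse = ", "))
  }
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab$length <- tab$end - tab$start
  if (any(tab$length <= 0L)) {
    stop("prophage regions must satisfy start < end")
  }
  tab[, c("genome_id", "replicon_id", "start", "end", "length")]
}

# ---- writers ----------------------------------------------------------------

#' Write result tables as deterministic TSV files
#'
#' Each table is written with a fixed column order and rows sorted by
#' `genome_id` then `gene_id` (falling back to the first column when those
#' are absent), so the same inputs always produce byte-identical files.
#'
#' @param tables named list of data.frames.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    sort_cols <- intersect(c("genome_id", "gene_id"), names(tab))
    if (!length(sort_cols) && ncol(tab)) sort_cols <- names(tab)[[1]]
    if (nrow(tab) && length(sort_cols)) {
      tab <- tab[do.call(order, c(unname(tab[sort_cols]), list(method = "radix"))), ,
                 drop = FALSE]
    }
    path <- file.path(dir, paste0(nm, ".tsv"))
    write_tsv_deterministic(tab, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

write_tsv_deterministic <- function(tab, path) {
  # list columns (e.g. ct_domains) are flattened to comma-joined strings
  is_list <- vapply(tab, is.list, logical(1))
  for (j in which(is_list)) {
    tab[[j]] <- vapply(tab[[j]], function(x) paste(x, collapse = ","), character(1))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write a gene table in the tabular annotation dialect
#'
#' Inverse of [read_gene_table()] for the TSV dialect: internal 0-based
#' half-open coordinates are converted back to 1-based inclusive.
#'
#' @param genes gene data.frame (internal convention).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gene_table <- function(genes, path) {
  out <- genes[, c("gene_id", "genome_id", "replicon_id", "start", "end",
                   "strand", "aa_length", "product_label")]
  if (nrow(out)) {
    cc <- coords_to_onebased(out$start, out$end)
    out$start <- cc$start
    out$end <- cc$end
  }
  write_tsv_deterministic(out, path)
}
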