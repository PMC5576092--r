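# End-to-end orchestration: screen -> architecture -> context -> immunity ->
# statistics, with deterministic table output and ground-truth evaluation.

#' Four-way architecture label (Ct_MAD as its own class)
#'
#' The three-way class plus the Ct_MAD subtype of unknown extensions, i.e.
#' the labels the generator plants.
#'
#' @param arch architecture-classified MuF table.
#' @return character vector over SHORT/CT_TOXIN/CT_UNKNOWN/CT_MAD.
#' @export
architecture_label <- function(arch) {
  ifelse(arch$class == "CT_UNKNOWN" & arch$ctmad, "CT_MAD", arch$class)
}

#' Run the full MuF pipeline
#'
#' Executes every stage on a dataset (an in-memory `muf_dataset` or a bundle
#' directory written by [write_dataset()]): MuF protein calling,
#' architecture classification, genomic context and prophage association,
#' immunity-candidate flagging, summary tables, the paired association tests
#' and the family/toxin-domain network. When `outdir` is given, all tables
#' plus a run manifest are written as deterministic TSV files.
#'
#' @param dataset a `muf_dataset` or a path to a dataset bundle directory.
#' @param thresholds a [default_thresholds()] list.
#' @param toxin_catalog toxin-domain names (default: bundled catalog).
#' @param outdir optional output directory.
#' @param welch use the Welch t statistic in the paired tests.
#' @return list of class `muf_result`: `muf_proteins`, `architectures`,
#'   `contexts`, `candidates`, `summary`, `network`, `tests`, `lysogeny`,
#'   `manifest`.
#' @export
run_pipeline <- function(dataset, thresholds = default_thresholds(),
                         toxin_catalog = default_toxin_catalog()$name,
                         outdir = NULL, welch = TRUE) {
  if (is.character(dataset)) {
    dataset <- read_dataset(dataset)
  }
  stopifnot(inherits(dataset, "muf_dataset"))
  genes <- dataset$genes
  hits <- dataset$hits
  regions <- dataset$regions
  metadata <- dataset$metadata

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  muf <- run_stage("screen", call_muf_proteins(hits, genes))
  arch <- run_stage("architecture",
                    classify_architecture(muf, hits, toxin_catalog, thresholds))
  ctx <- run_stage("context",
                   context_profiles(arch, genes, hits, regions, metadata,
                                    thresholds))
  cand <- run_stage("immunity",
                    suppressWarnings(flag_candidates(arch, genes, thresholds)))
  lys <- run_stage("context", lysogeny_table(metadata, regions, thresholds))
  summaries <- run_stage("stats", {
    keys <- c("type", "clade", "phage_family", "lifestyle", "family")
    data.table::setDF(data.table::rbindlist(
      lapply(keys, function(k) summarize_groups(arch, metadata, k))))
  })
  tests <- run_stage("stats", suppressWarnings(
    paired_association_tests(arch, cand, metadata, welch = welch)))
  network <- run_stage("stats",
                       build_network(arch, thresholds$network_min_support))

  manifest <- data.frame(
    key = c("package", "version", "seed",
            names(unclass(thresholds)),
            "n_genes", "n_hits", "n_regions", "n_genomes"),
    value = c("mufscan",
              as.character(utils::packageVersion("mufscan")),
              if (is.null(dataset$spec)) "external" else
                as.character(dataset$spec$seed),
              vapply(unclass(thresholds), as.character, character(1)),
              as.character(c(nrow(genes), nrow(hits), nrow(regions),
                             nrow(metadata)))),
    stringsAsFactors = FALSE
  )

  result <- structure(
    list(muf_proteins = muf, architectures = arch, contexts = ctx,
         candidates = cand, summary = summaries, network = network,
         tests = tests, lysogeny = lys, manifest = manifest),
    class = "muf_result")

  if (!is.null(outdir)) {
    tryCatch(
      write_results(list(muf_proteins = arch, contexts = ctx,
                         candidates = cand, summary = summaries,
                         network = network, tests = tests,
                         lysogeny = lys, manifest = manifest),
                    outdir),
      error = function(e) {
        unlink(outdir, recursive = TRUE)
        stop("pipeline stage 'write' failed: ", conditionMessage(e),
             call. = FALSE)
      })
  }
  result
}

#' @export
print.muf_result <- function(x, ...) {
  cat("MuF pipeline result\n",
      "  MuF proteins: ", nrow(x$muf_proteins),
      " (", sum(x$architectures$class == "SHORT"), " short, ",
      sum(x$architectures$class == "CT_TOXIN"), " toxin, ",
      sum(x$architectures$class == "CT_UNKNOWN"), " unknown-extension)\n",
      "  network edges: ", nrow(x$network), "\n", sep = "")
  invisible(x)
}

# precision/recall of a binary call set against truth, by identifier
pr_binary <- function(called_ids, truth_ids) {
  tp <- length(intersect(called_ids, truth_ids))
  precision <- if (length(called_ids)) tp / length(called_ids) else 1
  recall <- if (length(truth_ids)) tp / length(truth_ids) else 1
  c(precision = precision, recall = recall)
}

#' Evaluate pipeline calls against ground truth
#'
#' Per-category precision and recall of MuF calls, family assignments,
#' architecture classes (four-way, Ct_MAD separate), prophage-association
#' categories, lysogen flags and small-ORF flags, against the generator's
#' ground-truth labels.
#'
#' @param result a `muf_result` from [run_pipeline()].
#' @param dataset the `muf_dataset` holding `truth_genes`/`truth_genomes`.
#' @return data.frame: `category`, `level`, `n_called`, `n_truth`,
#'   `precision`, `recall`.
#' @export
evaluate_calls <- function(result, dataset) {
  tg <- dataset$truth_genes
  tge <- dataset$truth_genomes
  if (is.null(tg) || is.null(tge)) stop("dataset carries no ground truth")
  if (!all(tg$genome_id %in% tge$genome_id)) {
    stop("ground-truth gene/genome id mismatch")
  }
  arch <- result$architectures
  rows <- list()
  add <- function(category, level, called_ids, truth_ids) {
    pr <- pr_binary(called_ids, truth_ids)
    rows[[length(rows) + 1L]] <<- data.frame(
      category = category, level = level,
      n_called = length(called_ids), n_truth = length(truth_ids),
      precision = pr[["precision"]], recall = pr[["recall"]],
      stringsAsFactors = FALSE)
  }

  add("muf_call", "any", arch$gene_id, tg$gene_id)
  for (fam in sort(unique(tg$family))) {
    add("family", fam, arch$gene_id[arch$family == fam],
        tg$gene_id[tg$family == fam])
  }
  lbl <- architecture_label(arch)
  for (cl in sort(unique(tg$architecture))) {
    add("architecture", cl, arch$gene_id[lbl == cl],
        tg$gene_id[tg$architecture == cl])
  }
  ctx <- result$contexts
  bact_truth <- tg[!is.na(tg$association), , drop = FALSE]
  for (cat in sort(unique(bact_truth$association))) {
    add("association", cat,
        ctx$gene_id[!is.na(ctx$association) & ctx$association == cat],
        bact_truth$gene_id[bact_truth$association == cat])
  }
  lys <- result$lysogeny
  bact <- tge[tge$type == "bacterium", , drop = FALSE]
  add("lysogen", "true",
      lys$genome_id[!is.na(lys$lysogen) & lys$lysogen],
      bact$genome_id[bact$lysogen])
  cand <- result$candidates
  add("small_orf", "true",
      cand$muf_gene_id[cand$is_small],
      tg$gene_id[!is.na(tg$planted_immunity) & tg$planted_immunity])

  data.table::setDF(data.table::rbindlist(rows))
}
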