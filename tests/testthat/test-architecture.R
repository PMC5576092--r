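test_that("extension length arithmetic and the 100-aa inclusive boundary", {
  expect_identical(ct_extension_length(300L, 150L), 150L)
  expect_identical(ct_extension_length(350L, 250L), 100L)
  expect_error(ct_extension_length(100L, 150L), "exceeds")

  genes <- make_genes(c(350L, 349L, 363L))
  calls <- data.frame(
    protein_id = genes$gene_id, genome_id = "G1", gene_id = genes$gene_id,
    family = "MUF1", muf_env_from = 1L, muf_env_to = 250L,
    aa_length = genes$aa_length, best_evalue = 1e-20,
    stringsAsFactors = FALSE)
  arch <- classify_architecture(calls, empty_hits())
  # exactly 100 aa counts as an extension; 99 does not; 113 does
  expect_identical(arch$ct_length, c(100L, 99L, 113L))
  expect_identical(arch$has_extension, c(TRUE, FALSE, TRUE))
  expect_identical(arch$class, c("CT_UNKNOWN", "SHORT", "CT_UNKNOWN"))
})

test_that("extension content decides the class", {
  genes <- make_genes(rep(400L, 4))
  calls <- data.frame(
    protein_id = genes$gene_id, genome_id = "G1", gene_id = genes$gene_id,
    family = "MUF2", muf_env_from = 1L, muf_env_to = 200L,
    aa_length = 400L, best_evalue = 1e-20, stringsAsFactors = FALSE)
  h <- make_hits(
    make_hit(genes$gene_id[1], "Ntox50", from = 250, to = 350),      # toxin in ext
    make_hit(genes$gene_id[2], "Ct_MAD", from = 260, to = 340),      # Ct_MAD in ext
    make_hit(genes$gene_id[3], "Ntox50", from = 10, to = 120)        # toxin N-terminal
  )
  arch <- classify_architecture(calls, h)
  expect_identical(arch$class, c("CT_TOXIN", "CT_UNKNOWN", "CT_UNKNOWN",
                                 "CT_UNKNOWN"))
  expect_identical(arch$ctmad, c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(arch$ct_domains[1], "Ntox50")
  expect_identical(architecture_label(arch),
                   c("CT_TOXIN", "CT_MAD", "CT_UNKNOWN", "CT_UNKNOWN"))
})

test_that("short proteins stay short whatever their hits", {
  genes <- make_genes(220L)
  calls <- data.frame(
    protein_id = genes$gene_id, genome_id = "G1", gene_id = genes$gene_id,
    family = "MUF1", muf_env_from = 1L, muf_env_to = 200L,
    aa_length = 220L, best_evalue = 1e-20, stringsAsFactors = FALSE)
  h <- make_hits(make_hit(genes$gene_id[1], "Ntox50", from = 205, to = 215))
  arch <- classify_architecture(calls, h)
  expect_identical(arch$class, "SHORT")
  expect_false(arch$ctmad)
})

test_that("toxin catalog tables load, deduplicate, and reject conflicts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tactivity", "Ntox50\tnuclease", "Ntox50\tnuclease"), path)
  cat1 <- toxin_catalog_from_table(path)
  expect_identical(cat1$name, "Ntox50")

  writeLines(c("name\tactivity", "Ntox50\tnuclease", "Ntox50\tpeptidase"), path)
  expect_error(toxin_catalog_from_table(path), "conflicting")

  writeLines("name\tactivity", path)
  empty_cat <- toxin_catalog_from_table(path)
  expect_identical(nrow(empty_cat), 0L)
})

test_that("classes partition the calls and the catalog acts monotonically", {
  set.seed(33)
  ds <- generate_dataset(synthetic_spec(seed = 90, n_phage_genomes = 60,
                                        n_bacterial_genomes = 0,
                                        p_muf_phage = 0.9, p_false_hit = 0))
  calls <- call_muf_proteins(ds$hits, ds$genes)
  full <- classify_architecture(calls, ds$hits)
  expect_true(all(full$class %in% c("SHORT", "CT_TOXIN", "CT_UNKNOWN")))
  expect_identical(sum(table(full$class)), nrow(calls))

  # with an empty catalog every extension is CT_UNKNOWN ...
  none <- classify_architecture(calls, ds$hits, toxin_catalog = character())
  expect_false(any(none$class == "CT_TOXIN"))
  # ... and enlarging the catalog never demotes CT_TOXIN to CT_UNKNOWN
  half <- classify_architecture(calls, ds$hits,
                                toxin_catalog = default_toxin_catalog()$name[1:4])
  was_toxin <- half$protein_id[half$class == "CT_TOXIN"]
  expect_true(all(full$class[full$protein_id %in% was_toxin] == "CT_TOXIN"))
})
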