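test_that("specs validate their probabilities, mixes and length range", {
  expect_error(synthetic_spec(), "seed")
  expect_error(synthetic_spec(seed = 1, p_muf_phage = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_spec(seed = 1,
                              architecture_mix = c(SHORT = 0.7, CT_TOXIN = 0.7,
                                                   CT_UNKNOWN = 0, CT_MAD = 0)),
               "sum to 1")
  # a range that cannot produce remnants is a configuration error
  expect_error(synthetic_spec(seed = 1,
                              prophage_len_range = c(19000L, 45000L)),
               "straddle 18 kb")
  expect_error(synthetic_spec(seed = 1,
                              prophage_len_range = c(2000L, 17000L)),
               "straddle 18 kb")
  # with no remnants requested, an all-large range is fine
  expect_s3_class(synthetic_spec(seed = 1,
                                 assoc_mix = c(IN_PROPHAGE = 1, IN_REMNANT = 0,
                                               NEAR_PACKAGING = 0, UNASSOCIATED = 0),
                                 prophage_len_range = c(19000L, 45000L)),
                  "muf_synth_spec")
})

test_that("generation is deterministic: same spec and seed, identical bundles", {
  spec <- synthetic_spec(seed = 17, n_phage_genomes = 15,
                         n_bacterial_genomes = 15)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(spec), d1)
  write_dataset(generate_dataset(spec), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", n = 10e6),
                     readBin(file.path(d2, f), "raw", n = 10e6))
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  write_dataset(generate_dataset(synthetic_spec(seed = 18,
                                                n_phage_genomes = 15,
                                                n_bacterial_genomes = 15)), d3)
  expect_false(identical(readBin(file.path(d1, "genes.tsv"), "raw", 10e6),
                         readBin(file.path(d3, "genes.tsv"), "raw", 10e6)))
})

test_that("a degenerate all-short mix plants no toxins and no immunity ORFs", {
  ds <- generate_dataset(synthetic_spec(
    seed = 5, n_phage_genomes = 40, n_bacterial_genomes = 0,
    architecture_mix = c(SHORT = 1, CT_TOXIN = 0, CT_UNKNOWN = 0, CT_MAD = 0),
    p_small_orf_given_short = 0, p_false_hit = 0))
  expect_true(all(ds$truth_genes$architecture == "SHORT"))
  expect_false(any(ds$truth_genes$planted_immunity))
  expect_false(any(ds$hits$profile_class %in% c("TOXIN", "CT_MAD")))
})

test_that("planted muf counts follow the configured binomial", {
  n <- 1000; p <- 0.35
  ds <- generate_dataset(synthetic_spec(seed = 29, n_phage_genomes = n,
                                        n_bacterial_genomes = 0,
                                        p_muf_phage = p))
  k <- sum(ds$truth_genomes$has_muf)
  expect_lt(abs(k / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("planted muf genes sit inside a complete packaging module", {
  ds <- generate_dataset(synthetic_spec(seed = 42, n_phage_genomes = 50,
                                        n_bacterial_genomes = 0,
                                        p_muf_phage = 1, p_false_hit = 0))
  markers <- marker_genes(ds$hits, ds$genes)
  offsets <- as.integer(names(ds$spec$muf_offset_dist))
  for (i in seq_len(nrow(ds$truth_genes))) {
    muf <- ds$genes[ds$genes$gene_id == ds$truth_genes$gene_id[i], ]
    mrk <- markers[markers$replicon_id == muf$replicon_id, ]
    expect_setequal(mrk$marker_class, c("PORTAL", "TLS", "TSS"))
    d_portal <- mrk$rank[mrk$marker_class == "PORTAL"] - muf$rank
    expect_true(-d_portal %in% offsets)   # muf offset from the portal gene
    expect_true(all(abs(mrk$rank - muf$rank) <= 10))
  }
})

test_that("toxin muf genes get a same-direction downstream gene as configured", {
  ds <- generate_dataset(synthetic_spec(
    seed = 8, n_phage_genomes = 60, n_bacterial_genomes = 0, p_muf_phage = 1,
    p_small_orf_given_toxin = 1, p_false_hit = 0,
    architecture_mix = c(SHORT = 0, CT_TOXIN = 1, CT_UNKNOWN = 0, CT_MAD = 0)))
  for (i in seq_len(nrow(ds$truth_genes))) {
    muf <- ds$genes[ds$genes$gene_id == ds$truth_genes$gene_id[i], ]
    ds_gene <- downstream_gene(ds$genes, muf)
    expect_false(is.null(ds_gene))
    expect_lt(ds_gene$aa_length, 150L)
  }
})

test_that("fixtures are deterministic and cover their contracts", {
  fx1 <- make_fixture("minimal")
  fx2 <- make_fixture("minimal")
  expect_identical(fx1$genes, fx2$genes)
  expect_identical(fx1$hits, fx2$hits)
  expect_true(all(c("SHORT", "CT_TOXIN", "CT_UNKNOWN", "CT_MAD") %in%
                    fx1$truth_genes$architecture))
  expect_true(any(fx1$regions$length > 18000))
  expect_true(any(fx1$regions$length <= 18000))
  expect_true("NEAR_PACKAGING" %in% fx1$truth_genes$association)

  fe <- make_fixture("empty")
  expect_identical(nrow(fe$truth_genes), 0L)
  expect_error(make_fixture("nope"))
})
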