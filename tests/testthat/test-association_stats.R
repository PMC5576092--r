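test_that("two-tailed Fisher p matches enumeration and the stated examples", {
  expect_equal(fisher_exact_two_tailed(5, 5, 5, 5), 1.0)
  # support of [[3,0],[0,3]]: x = 0 and x = 3 each have probability 1/20
  expect_equal(fisher_exact_two_tailed(3, 0, 0, 3), 0.1)
  expect_equal(fisher_exact_two_tailed(1, 9, 11, 3), oracle_fisher(1, 9, 11, 3),
               tolerance = 1e-10)
  expect_equal(fisher_exact_two_tailed(1, 9, 11, 3), 0.002759456,
               tolerance = 1e-6)
  expect_warning(p <- fisher_exact_two_tailed(0, 0, 3, 4), "zero margin")
  expect_identical(p, 1)
  expect_error(fisher_exact_two_tailed(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher p agrees with the reference implementation on random tables", {
  set.seed(99)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_two_tailed(tab[1, 1], tab[1, 2],
                                         tab[2, 1], tab[2, 2]),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("t statistics match closed forms and the reference implementation", {
  x <- c(2.1, 2.5, 2.9); y <- c(3.2, 3.6, 4.0)
  got <- two_sample_t(x, y, welch = FALSE)
  expect_equal(got$t, oracle_pooled_t(x, y), tolerance = 1e-12)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)

  got_w <- two_sample_t(x, y + 0.01 * seq_along(y), welch = TRUE)
  ref_w <- stats::t.test(x, y + 0.01 * seq_along(y))
  expect_equal(got_w$t, unname(ref_w$statistic), tolerance = 1e-12)
  expect_equal(got_w$df, unname(ref_w$parameter), tolerance = 1e-12)

  # identical samples: t = 0, p = 1
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3), welch = FALSE)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # p decreases monotonically as the shift grows, variance held fixed
  ps <- vapply(c(1, 5, 10), function(s) {
    two_sample_t(c(1, 2, 3), c(1, 2, 3) + s, welch = FALSE)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))

  expect_error(two_sample_t(1, c(1, 2)), "at least two")
  expect_error(two_sample_t(c(1, 1), c(2, 2)), "degenerate")
})

make_tox_arch <- function(families, domains) {
  data.frame(protein_id = sprintf("p%03d", seq_along(families)),
             genome_id = "G1", gene_id = sprintf("p%03d", seq_along(families)),
             family = families, muf_env_from = 1L, muf_env_to = 200L,
             aa_length = 400L, best_evalue = 1e-20, ct_length = 200L,
             has_extension = TRUE, class = "CT_TOXIN",
             ct_domains = domains, ctmad = FALSE, stringsAsFactors = FALSE)
}

test_that("the network keeps toxin domains with at least min_support proteins", {
  arch <- make_tox_arch(c(rep("MUF1", 7), rep("MUF2", 4)),
                        c(rep("Ntox50", 7), rep("EndoU_bacteria", 4)))
  net <- build_network(arch, min_support = 5)
  expect_identical(nrow(net), 1L)
  expect_identical(net$muf_family, "MUF1")
  expect_identical(net$weight, 7L)

  # support counts the domain across families
  arch <- make_tox_arch(c(rep("MUF1", 3), rep("MUF2", 3)), rep("Ntox50", 6))
  net <- build_network(arch, min_support = 5)
  expect_identical(nrow(net), 2L)
  expect_identical(sum(net$weight), 6L)

  # a protein with two catalog domains contributes to two edges
  arch <- make_tox_arch(rep("MUF1", 5), rep("Ntox50,EndoU_bacteria", 5))
  net <- build_network(arch, min_support = 5)
  expect_identical(nrow(net), 2L)
  expect_identical(sum(net$weight), 10L)

  expect_identical(nrow(build_network(arch[0, ])), 0L)
})

test_that("summary rows conserve counts and proportions", {
  ds <- make_fixture("minimal")
  res <- run_pipeline(ds)
  s <- res$summary
  expect_true(all(s$n_short + s$n_toxin + s$n_unknown == s$n_muf))
  expect_true(all(s$prop_muf_pos >= 0 & s$prop_muf_pos <= 1, na.rm = TRUE))
  expect_true(all(s$n_muf_pos <= s$n_genomes |
                    s$grouping == "family"))
  # a grouping level fully covered by MuF genomes reports proportion 1
  fam_rows <- s[s$grouping == "family", ]
  expect_true(all(fam_rows$n_muf >= 1))
  expect_error(summarize_groups(res$architectures, ds$metadata, "nope"),
               "unknown grouping")
})

test_that("paired association tests detect planted effects and stay deterministic", {
  ds <- generate_dataset(synthetic_spec(seed = 301, n_phage_genomes = 300,
                                        n_bacterial_genomes = 200,
                                        p_false_hit = 0))
  res <- run_pipeline(ds)
  tests <- res$tests
  expect_identical(nrow(tests), 5L)
  # the study regime plants toxin/Firmicutes, muf/Siphoviridae and
  # muf/temperate enrichments
  p <- setNames(tests$p_value, tests$test)
  expect_lt(p[["toxin_vs_short_firmicutes"]], 0.01)
  expect_lt(p[["muf_siphoviridae"]], 0.01)
  expect_lt(p[["muf_temperate"]], 0.01)
  expect_lt(p[["downstream_orf_length_toxin_vs_short"]], 0.01)
  # deterministic given inputs
  res2 <- run_pipeline(ds)
  expect_identical(res$tests, res2$tests)
  # missing metadata columns are reported
  md <- ds$metadata; md$clade <- NULL
  expect_error(paired_association_tests(res$architectures, res$candidates, md),
               "clade")
})
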