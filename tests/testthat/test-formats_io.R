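test_that("coordinate conversion is an exact bijection", {
  set.seed(11)
  s1 <- sample.int(1e6, 200)
  e1 <- s1 + sample.int(5000, 200)
  internal <- coords_to_internal(s1, e1)
  expect_true(all(internal$start == s1 - 1L))
  expect_true(all(internal$end == e1))
  back <- coords_to_onebased(internal$start, internal$end)
  expect_identical(back$start, as.integer(s1))
  expect_identical(back$end, as.integer(e1))
  expect_error(coords_to_internal(0, 10), "1 <= start")
  expect_error(coords_to_onebased(5, 5), "start < end")
})

test_that("gene tables parse, sort by coordinate, and derive protein length", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene_id\tgenome_id\treplicon_id\tstart\tend\tstrand",
    "gB\tG1\tR1\t500\t801\t-",       # second by coordinate, listed first
    "gA\tG1\tR1\t1\t300\t+"
  ), path)
  genes <- read_gene_table(path)
  expect_identical(genes$gene_id, c("gA", "gB"))     # coordinate order wins
  expect_identical(genes$rank, c(0L, 1L))
  # 1..300 converts to [0, 300); aa = 300/3 - 1 for a stop-inclusive CDS
  expect_identical(genes$start[1], 0L)
  expect_identical(genes$end[1], 300L)
  expect_identical(genes$aa_length[1], 99L)
})

test_that("gene table round-trips through write and read", {
  genes <- make_genes(c(120L, 310L, 95L), genome = "G9",
                      strand = c("+", "-", "+"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(genes, path)
  back <- read_gene_table(path)
  expect_equal(back, genes, ignore_attr = TRUE)
})

test_that("empty and malformed gene tables are handled", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene_id\tgenome_id\treplicon_id\tstart\tend\tstrand", path)
  expect_identical(nrow(read_gene_table(path)), 0L)

  writeLines(c("gene_id\tgenome_id\treplicon_id\tstart\tend\tstrand",
               "g1\tG1\tR1\t1"), path)
  expect_error(read_gene_table(path), "line 2")

  writeLines(c("gene_id\tgenome_id\treplicon_id\tstart\tend\tstrand",
               "g1\tG1\tR1\t1\t300\t+",
               "g1\tG1\tR1\t400\t600\t+"), path)
  expect_error(read_gene_table(path), "duplicate gene_id")
})

test_that("domtblout lines parse to the hand-read column values", {
  path <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(c(
    "# comment line",
    paste("PHG0001_g0005 - 412 MuF1 - 245 3.1e-42 140.2 0.1",
          "1 1 5.2e-45 6.1e-42 139.8 0.1 2 240 12 250 10 255 0.97",
          "MuF-domain protein")
  ), path)
  hits <- read_domtblout(path)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$protein_id, "PHG0001_g0005")
  expect_identical(hits$profile_name, "MuF1")
  expect_identical(hits$profile_class, "MUF1")
  expect_equal(hits$full_evalue, 3.1e-42)
  expect_equal(hits$bitscore, 140.2)
  expect_identical(hits$env_from, 10L)
  expect_identical(hits$env_to, 255L)
  expect_true(hits$passed_ga)
})

test_that("domtblout comment-only files and truncated lines behave per contract", {
  path <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(c("# only", "# comments"), path)
  expect_identical(nrow(read_domtblout(path)), 0L)

  writeLines("p1 - 100 MuF1 - 200 1e-10 50 0 1", path)  # 10 columns
  expect_error(read_domtblout(path), ">= 23 columns")
})

test_that("domtblout written by the generator round-trips", {
  hits <- make_hits(make_hit("p1", "MuF2", 1e-21, 88.4, 3, 190),
                    make_hit("p2", "Phage_portal", 2e-30, 200.1, 5, 305))
  path <- withr::local_tempfile(fileext = ".domtblout")
  write_domtblout(hits, path)
  back <- read_domtblout(path)
  expect_identical(back$protein_id, hits$protein_id)
  expect_identical(back$profile_name, hits$profile_name)
  expect_identical(back$profile_class, hits$profile_class)
  expect_identical(back$env_from, hits$env_from)
  expect_identical(back$env_to, hits$env_to)
  expect_equal(back$full_evalue, hits$full_evalue, tolerance = 1e-2)
})

test_that("raw-mode domtblout hits are not marked GA-passing", {
  hits <- make_hits(make_hit("p1", "MuF1"))
  path <- withr::local_tempfile(fileext = ".domtblout")
  write_domtblout(hits, path)
  expect_false(any(read_domtblout(path, raw = TRUE)$passed_ga))
})

test_that("result writing is deterministic and sorts rows", {
  tab <- data.frame(genome_id = c("B", "A"), gene_id = c("g2", "g1"),
                    value = c(2, 1), stringsAsFactors = FALSE)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_results(list(t = tab), d1)
  write_results(list(t = tab[2:1, ]), d2)
  expect_identical(readLines(file.path(d1, "t.tsv")),
                   readLines(file.path(d2, "t.tsv")))
  out <- utils::read.table(file.path(d1, "t.tsv"), header = TRUE, sep = "\t")
  expect_identical(out$genome_id, c("A", "B"))
  # empty tables still produce a header-only file
  d3 <- withr::local_tempdir()
  write_results(list(t = tab[0, ]), d3)
  expect_identical(length(readLines(file.path(d3, "t.tsv"))), 1L)
})

test_that("prophage region tables compute lengths and reject bad intervals", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\treplicon_id\tstart\tend",
               "B1\tB1_chr\t1000\t21000"), path)
  reg <- read_prophage_regions(path)
  expect_identical(reg$length, 20000L)
  writeLines(c("genome_id\treplicon_id\tstart\tend",
               "B1\tB1_chr\t1000\t1000"), path)
  expect_error(read_prophage_regions(path), "start < end")
})
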