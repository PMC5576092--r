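Package: mufscan
Title: Mining Phage-Encoded MuF Polymorphic Toxins from Domain-Hit Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics pipeline for identifying the MuF family of
    phage-encoded polymorphic toxins. Reads per-genome gene annotation tables,
    HMMER3 per-domain hit tables (domtblout) and prophage region tables; calls
    MuF-domain proteins with a single best-profile family assignment;
    classifies their C-terminal architecture (short, toxin extension, unknown
    extension, Ct_MAD); profiles the gene neighbourhood of muf genes relative
    to portal and terminase genes; assigns prophage-association categories and
    lysogeny; flags candidate immunity ORFs downstream of muf genes; and
    computes association statistics, summary tables and the MuF-family to
    toxin-domain network. Includes a seeded synthetic-data generator with
    ground truth so the whole pipeline is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
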