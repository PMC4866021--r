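test_that("interchange files load row-for-row and enforce the schema", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rows <- tibble::tibble(
    source_db = "mirtarbase",
    mirna_id = c("hsa-miR-1-3p", "mmu-miR-2", "hsa-let-7a"),
    mirbase_acc = "",
    target_symbol = c("GENE1", "GENE2", "GENE1"),
    species = c("hsa", "mmu", "hsa"),
    methods = c("qPCR", "Western blot;qPCR", "NGS"),
    clip_support = ""
  )
  write_db_file(rows, f)
  recs <- read_mti_db(f, "mirtarbase")
  expect_equal(nrow(recs), 3)
  expect_equal(recs$methods[[2]], c("Western blot", "qPCR"))
  expect_equal(recs$clip_support, c(0L, 0L, 0L))

  # missing mandatory column aborts naming it
  bad <- rows[setdiff(names(rows), "species")]
  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(bad, f2)
  expect_error(read_mti_db(f2, "mirtarbase"), "species")
})

test_that("malformed rows are rejected, counted and reported", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rows <- tibble::tibble(
    source_db = c("tarbase", "tarbase", "tarbase", "tarbase"),
    mirna_id = c("hsa-miR-1", "hsa-miR-2", "", "hsa-miR-4"),
    mirbase_acc = c("", "", "", ""),
    target_symbol = c("GENE1", "GENE2", "GENE3", ""),
    species = c("hsa", "hsa", "hsa", "hsa"),
    methods = "qPCR",
    clip_support = c("", "5", "", "")
  )
  write_db_file(rows, f)
  recs <- suppressMessages(read_mti_db(f, "tarbase"))
  expect_equal(nrow(recs), 1)
  rejected <- attr(recs, "rejected")
  expect_equal(nrow(rejected), 3)
  expect_setequal(rejected$reason,
                  c("clip_support set outside starbase",
                    "neither mirna_id nor mirbase_acc",
                    "empty target_symbol"))
})

test_that("planted malformed rows in generated fixtures are all caught", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(n_mirnas = 20, n_targets = 30,
                       occurrence_histogram = c("1" = 60, "2" = 20,
                                                "3" = 10, "4" = 3),
                       n_malformed = 7, seed = 5)
  m <- generate_reference(spec, dir)
  total_ok <- 0L
  total_bad <- 0L
  for (db in c("tarbase", "mirtarbase", "mirecords", "starbase")) {
    recs <- suppressMessages(read_mti_db(m$files[[db]], db))
    total_ok <- total_ok + nrow(recs)
    bad <- nrow(attr(recs, "rejected"))
    expect_equal(bad, m$n_malformed_by_db[[db]])
    total_bad <- total_bad + bad
  }
  expect_equal(total_bad, 7)
  expect_equal(total_ok, sum(m$per_db_rows$n))
})

test_that("miRBase accessions resolve to identifiers with drop-and-count", {
  acc <- tibble::tibble(accession = "MIMAT0000001",
                        mirna_id = "hsa-miR-1-3p")
  recs <- make_records("tarbase", c("", "", "hsa-miR-9"),
                       c("GENE1", "GENE2", "GENE3"), "hsa",
                       mirbase_acc = c("MIMAT0000001", "MIMAT9999999", ""))
  out <- suppressMessages(resolve_accessions(recs, acc))
  expect_equal(attr(out, "n_dropped"), 1L)
  expect_equal(sort(out$mirna_id), c("hsa-miR-1-3p", "hsa-miR-9"))

  # fixture-scale: planted unmappables all drop, everything else survives
  dir <- withr::local_tempdir()
  spec <- fixture_spec(n_mirnas = 25, n_targets = 40,
                       occurrence_histogram = c("1" = 40, "2" = 10),
                       n_unmappable = 10, seed = 8)
  m <- generate_reference(spec, dir)
  tb <- suppressMessages(read_mti_db(m$files$tarbase, "tarbase"))
  res <- suppressMessages(
    resolve_accessions(tb, read_accession_table(m$files$accessions))
  )
  expect_equal(attr(res, "n_dropped"), 10L)
  expect_equal(nrow(res), nrow(tb) - 10)
})

test_that("symbol mapping matches symbols, synonyms and cross-references case-insensitively", {
  up <- tiny_uniprot()
  hit <- map_symbol_to_uniprot("gene1", "hsa", up)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$accession,
               up$accession[up$gene_symbol == "GENE1" & up$species == "hsa"])

  # agnostic: one accession per species hosting the symbol
  ag <- map_symbol_to_uniprot("GENE1", uniprot = up, agnostic = TRUE)
  expect_equal(nrow(ag), 3)
  expect_setequal(ag$accession_species, c("hsa", "mmu", "dre"))

  syn <- map_symbol_to_uniprot("syn-gene2", "mmu", up)
  expect_equal(syn$accession,
               up$accession[up$gene_symbol == "GENE2" & up$species == "mmu"])
  xr <- map_symbol_to_uniprot(paste0("xr-", up$accession[5]), up$species[5], up)
  expect_equal(xr$accession, up$accession[5])

  expect_equal(nrow(map_symbol_to_uniprot("NOSUCH", "hsa", up)), 0)
})

test_that("harmonize pools records into occurrence strings in fixed bit order", {
  up <- tiny_uniprot()
  recs <- dplyr::bind_rows(
    make_records("tarbase", "hsa-miR-1-3p", "GENE1", "hsa"),
    make_records("starbase", "hsa-miR-1-3p", "GENE1", "hsa",
                 methods = "CLIP-Seq", clip_support = 2L),
    make_records("mirtarbase", "hsa-miR-2", "GENE2", "hsa")
  )
  linked <- harmonize_mtis(recs, up, match_policy())
  pair1 <- linked[linked$accession ==
                    up$accession[up$gene_symbol == "GENE1" &
                                   up$species == "hsa"], ]
  expect_equal(pair1$sources, "1001")   # (tarbase, mirtarbase, mirecords, starbase)
  expect_equal(pair1$n_dbs, 2L)
  pair2 <- linked[linked$mirna_key == "hsa-mir-2", ]
  expect_equal(pair2$sources, "0100")
  expect_equal(pair2$n_dbs, 1L)
})

test_that("agnostic mapping fans out one record per homologous accession", {
  up <- tiny_uniprot()
  recs <- make_records("mirecords", "hsa-miR-5", "GENE3", "hsa")
  sp <- harmonize_mtis(recs, up, agnostic = FALSE)
  ag <- harmonize_mtis(recs, up, agnostic = TRUE)
  expect_equal(nrow(sp), 1)
  expect_equal(nrow(ag), 3)  # fan-out equals the mapping-set size
  # agnostic output is a superset of the species-specific output
  expect_true(all(paste(sp$mirna_key, sp$accession, sp$sources) %in%
                    paste(ag$mirna_key, ag$accession, ag$sources)))
})

test_that("conservation and idempotence hold on generated fixtures", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(n_mirnas = 20, n_targets = 35, n_species = 3,
                       occurrence_histogram = c("1" = 25, "2" = 10,
                                                "3" = 6, "4" = 2),
                       seed = 13)
  m <- generate_reference(spec, dir)
  recs <- dplyr::bind_rows(lapply(
    c("tarbase", "mirtarbase", "mirecords", "starbase"),
    function(db) suppressMessages(read_mti_db(m$files[[db]], db))
  ))
  recs <- suppressMessages(
    resolve_accessions(recs, read_accession_table(m$files$accessions))
  )
  up <- read_uniprot_table(m$files$uniprot)
  pol <- match_policy(ignore_species_prefix = TRUE, cluster_arms = TRUE)
  linked <- harmonize_mtis(recs, up, pol)

  # conservation: total set bits equal surviving (db, key, accession) events
  expect_equal(sum(linked$n_dbs), attr(linked, "n_events"))
  expect_equal(sum(linked$n_dbs), sum(m$pairs$popcount))

  # idempotence: expanding each linked pair back to one record per set bit
  # and re-harmonizing reproduces identical occurrence strings
  expanded <- linked |>
    dplyr::left_join(up[c("accession", "gene_symbol", "species")],
                     by = c("accession", "species")) |>
    dplyr::rowwise() |>
    dplyr::mutate(dbs = list(c("tarbase", "mirtarbase", "mirecords",
                               "starbase")[strsplit(sources, "")[[1]] == "1"])) |>
    dplyr::ungroup() |>
    tidyr::unnest("dbs")
  recs2 <- make_records(expanded$dbs, expanded$mirna_key,
                        expanded$gene_symbol, expanded$species)
  linked2 <- harmonize_mtis(recs2, up, pol)
  expect_equal(linked2[c("mirna_key", "accession", "sources")],
               linked[c("mirna_key", "accession", "sources")])
})
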