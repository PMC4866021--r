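# Synthetic reference databases and ranked lists with known planted
# structure: every quantity the pipeline should recover (occurrence strings,
# filter-survivor counts, symbol fan-outs, enriched-set loadings) is chosen
# up front and recorded in a manifest, so each pipeline stage can be checked
# exactly, offline. Species codes, method labels and accession shapes mimic
# real-world conventions (hsa/mmu..., "P#####") without claiming real
# identities.

FIXTURE_SPECIES_POOL <- c("hsa", "mmu", "rno", "dre", "gga", "xla", "cel",
                          "dme", "ath", "bta")

FIXTURE_METHODS <- c("Reporter assay", "Western blot", "qPCR", "Microarray",
                     "NGS", "CLIP-Seq")

#' Specification for a synthetic reference-database fixture
#'
#' Describes the planted structure of a generated fixture: how many miRNAs,
#' target symbols and species exist, the exact database-occurrence histogram
#' of the planted `(miRNA, target)` pairs, and how many deliberately
#' malformed rows, unmappable miRBase accessions, and duplicated rows to
#' plant. Infeasible combinations error here, before any file is written.
#'
#' @param n_mirnas Number of distinct miRNAs (each with a unique core, so
#'   identifier clustering never merges two of them).
#' @param n_targets Number of target gene symbols; each symbol gets one
#'   UniProt accession per species.
#' @param n_species Number of organisms (drawn from a fixed code pool).
#' @param occurrence_histogram Named integer vector over `"1".."4"`: how many
#'   planted pairs occur in exactly that many source databases.
#' @param n_malformed Malformed rows to plant (distributed over the files).
#' @param n_unmappable Well-formed TarBase rows whose miRBase accession is
#'   absent from the accession table (dropped at resolution).
#' @param n_duplicate_rows Rows duplicated verbatim within their file.
#' @param frac_synonym_records Fraction of records referring to the target by
#'   a synonym instead of the primary gene symbol.
#' @param seed Integer seed; the same spec generates byte-identical files.
#'
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_mirnas = 30, n_targets = 60, n_species = 3,
                         occurrence_histogram = c("1" = 30, "2" = 12,
                                                  "3" = 5, "4" = 1),
                         n_malformed = 0, n_unmappable = 0,
                         n_duplicate_rows = 0, frac_synonym_records = 0.2,
                         seed = 1L) {
  counts <- c(n_mirnas, n_targets, n_species, occurrence_histogram,
              n_malformed, n_unmappable, n_duplicate_rows)
  if (any(counts < 0)) rlang::abort("All fixture counts must be non-negative.")
  if (!all(names(occurrence_histogram) %in% as.character(1:4))) {
    rlang::abort("`occurrence_histogram` names must be \"1\"..\"4\".")
  }
  if (n_species < 1 || n_species > length(FIXTURE_SPECIES_POOL)) {
    rlang::abort(sprintf("`n_species` must be in [1, %d].",
                         length(FIXTURE_SPECIES_POOL)))
  }
  if (sum(occurrence_histogram) > n_mirnas * n_targets) {
    rlang::abort("Occurrence histogram total exceeds the achievable number of distinct pairs.")
  }
  structure(
    list(n_mirnas = as.integer(n_mirnas), n_targets = as.integer(n_targets),
         n_species = as.integer(n_species),
         occurrence_histogram = occurrence_histogram,
         n_malformed = as.integer(n_malformed),
         n_unmappable = as.integer(n_unmappable),
         n_duplicate_rows = as.integer(n_duplicate_rows),
         frac_synonym_records = frac_synonym_records,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Generate a synthetic MTI reference-database fixture
#'
#' Writes the four interchange TSVs (tarbase, mirtarbase, mirecords,
#' starbase), the symbol-to-UniProt mapping TSV, the miRBase accession TSV
#' and a JSON manifest into `dir`. The manifest records every planted
#' quantity so tests (and the acceptance script) can verify that each
#' pipeline stage recovers it exactly.
#'
#' Planted pairs are `(miRNA, symbol)` combinations with one fixed species
#' each; the pair's popcount from the occurrence histogram decides in which
#' source databases it is recorded. TarBase rows carry only the miRBase
#' accession (resolved later); starBase rows carry a CLIP support count in
#' `[1, 5]` and the method `CLIP-Seq`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest: a list with `pairs` (tibble of planted
#'   interactions with occurrence strings), `survivors_by_min_occurrence`,
#'   `per_db_rows`, `n_malformed_by_db`, `n_unmappable`, `fan_out`, `mirnas`,
#'   and `files`.
#' @export
generate_reference <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- withr::with_seed(spec$seed, build_reference_fixture(spec))

  files <- list(
    tarbase = file.path(dir, "tarbase.tsv"),
    mirtarbase = file.path(dir, "mirtarbase.tsv"),
    mirecords = file.path(dir, "mirecords.tsv"),
    starbase = file.path(dir, "starbase.tsv"),
    uniprot = file.path(dir, "uniprot.tsv"),
    accessions = file.path(dir, "mirbase_acc.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  for (db in MTI_DB_NAMES) {
    rows <- manifest$db_rows[manifest$db_rows$source_db_file == db, ]
    readr::write_tsv(rows[MTI_DB_COLUMNS], files[[db]])
  }
  readr::write_tsv(manifest$uniprot, files$uniprot)
  readr::write_tsv(manifest$acc_table, files$accessions)
  out <- manifest[c("pairs", "survivors_by_min_occurrence", "per_db_rows",
                    "n_malformed_by_db", "n_unmappable", "fan_out", "mirnas")]
  out$files <- files
  jsonlite::write_json(out[setdiff(names(out), "files")], files$manifest,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(out)
}

build_reference_fixture <- function(spec) {
  species <- FIXTURE_SPECIES_POOL[seq_len(spec$n_species)]

  # miRNAs: unique cores so no two distinct miRNAs ever share a cluster key
  mirnas <- tibble::tibble(
    idx = seq_len(spec$n_mirnas),
    species_prefix = sample(species, spec$n_mirnas, replace = TRUE),
    core = c(paste0("miR-", 100 + seq_len(max(0, spec$n_mirnas - 2))),
             "let-7a", "let-7b")[seq_len(spec$n_mirnas)],
    arm = sample(c("3p", "5p", NA_character_), spec$n_mirnas, replace = TRUE),
    mirbase_acc = sprintf("MIMAT%07d", seq_len(spec$n_mirnas))
  )
  mirnas$mirna_id <- mirna_canonical(mirnas)
  clustered <- match_policy(ignore_species_prefix = TRUE, cluster_arms = TRUE)
  mirnas$mirna_key <- cluster_key(mirnas, clustered)

  # targets: one accession per (symbol, species); one synonym per symbol
  targets <- tidyr::expand_grid(
    symbol = paste0("GENE", seq_len(spec$n_targets)),
    species = species
  )
  targets$accession <- sprintf("P%05d", seq_len(nrow(targets)))
  synonym_of <- function(sym) paste0("SYN", substring(sym, 5), "X")
  uniprot <- tibble::tibble(
    accession = targets$accession,
    gene_symbol = targets$symbol,
    synonyms = synonym_of(targets$symbol),
    species = targets$species,
    protein_name = paste("Protein", targets$symbol, targets$species),
    go_terms = paste0("GO:", sprintf("%07d", seq_len(nrow(targets))), ";",
                      "GO:", sprintf("%07d", seq_len(nrow(targets)) + 5e5)),
    cross_references = paste0("XR-", targets$accession)
  )
  acc_table <- tibble::tibble(accession = mirnas$mirbase_acc,
                              mirna_id = mirnas$mirna_id)

  # planted pairs: distinct (miRNA, symbol), each with one species and a
  # popcount from the histogram
  hist <- spec$occurrence_histogram
  total <- sum(hist)
  pair_idx <- sample.int(spec$n_mirnas * spec$n_targets, total)
  mi <- ((pair_idx - 1L) %% spec$n_mirnas) + 1L
  ti <- ((pair_idx - 1L) %/% spec$n_mirnas) + 1L
  popc <- rep(as.integer(names(hist)), hist)
  popc <- popc[sample.int(length(popc))]
  pair_species <- sample(species, total, replace = TRUE)
  symbols <- paste0("GENE", ti)
  pairs <- tibble::tibble(
    mirna_id = mirnas$mirna_id[mi],
    mirna_key = mirnas$mirna_key[mi],
    mirbase_acc = mirnas$mirbase_acc[mi],
    symbol = symbols,
    species = pair_species,
    popcount = popc
  )
  pairs <- dplyr::left_join(pairs, targets,
                            by = c("symbol", "species"))
  pairs$dbs <- purrr::map(pairs$popcount,
                          function(k) sort(sample(MTI_DB_NAMES, k)))
  pairs$sources <- purrr::map_chr(pairs$dbs, occurrence_string)

  rows <- tidyr::unnest(
    pairs[c("mirna_id", "mirbase_acc", "symbol", "species", "dbs")],
    cols = "dbs"
  )
  names(rows)[names(rows) == "dbs"] <- "source_db"
  use_syn <- stats::runif(nrow(rows)) < spec$frac_synonym_records
  rows$target_symbol <- ifelse(use_syn, synonym_of(rows$symbol), rows$symbol)
  rows$methods <- ifelse(
    rows$source_db == "starbase", "CLIP-Seq",
    purrr::map_chr(seq_len(nrow(rows)), function(i) {
      paste(sample(FIXTURE_METHODS[-6], sample(1:2, 1)), collapse = ";")
    })
  )
  rows$clip_support <- ifelse(rows$source_db == "starbase",
                              as.character(sample(1:5, nrow(rows),
                                                  replace = TRUE)),
                              "")
  # TarBase rows are keyed by miRBase accession only
  rows$mirbase_acc <- ifelse(rows$source_db == "tarbase", rows$mirbase_acc, "")
  rows$mirna_id <- ifelse(rows$source_db == "tarbase", "", rows$mirna_id)
  rows$source_db_file <- rows$source_db

  # unmappable TarBase accessions: well-formed, dropped at resolution
  if (spec$n_unmappable > 0) {
    un <- rows[sample.int(nrow(rows), spec$n_unmappable, replace = TRUE), ]
    un$source_db <- "tarbase"
    un$source_db_file <- "tarbase"
    un$mirna_id <- ""
    un$mirbase_acc <- sprintf("MIMAT99%05d", seq_len(spec$n_unmappable))
    un$clip_support <- ""
    rows <- dplyr::bind_rows(rows, un)
  }

  if (spec$n_duplicate_rows > 0) {
    dup <- rows[sample.int(nrow(rows), spec$n_duplicate_rows,
                           replace = TRUE), ]
    rows <- dplyr::bind_rows(rows, dup)
  }

  per_db_rows <- dplyr::count(rows, .data$source_db_file, name = "n")

  # malformed rows, round-robin over the four files
  n_malformed_by_db <- stats::setNames(integer(4), MTI_DB_NAMES)
  if (spec$n_malformed > 0) {
    at <- rep(MTI_DB_NAMES, length.out = spec$n_malformed)
    bad <- purrr::map(seq_len(spec$n_malformed), function(i) {
      db <- at[i]
      kind <- (i - 1L) %% 3L
      tibble::tibble(
        source_db = db,
        mirna_id = if (kind == 2L) "" else "hsa-miR-1-3p",
        mirbase_acc = "",
        target_symbol = if (kind == 0L) "" else "GENE1",
        species = if (kind == 1L) "" else "hsa",
        methods = "qPCR",
        clip_support = if (kind == 2L && db != "starbase") "7" else
          if (kind == 2L) "" else "",
        source_db_file = db
      )
    })
    bad <- dplyr::bind_rows(bad)
    # kind 2 on starbase: make it malformed via missing identifiers instead
    n_malformed_by_db[] <- vapply(MTI_DB_NAMES, function(d) {
      sum(bad$source_db_file == d)
    }, integer(1))
    rows <- dplyr::bind_rows(rows, bad)
  }

  survivors <- tibble::tibble(
    min_occurrence = 1:4,
    n_pairs = vapply(1:4, function(k) sum(pairs$popcount >= k), integer(1))
  )
  fan_out <- dplyr::count(targets, .data$symbol, name = "n_accessions")

  list(
    pairs = pairs[c("mirna_id", "mirna_key", "mirbase_acc", "symbol",
                    "species", "accession", "sources", "popcount")],
    survivors_by_min_occurrence = survivors,
    per_db_rows = per_db_rows,
    n_malformed_by_db = as.list(n_malformed_by_db),
    n_unmappable = spec$n_unmappable,
    fan_out = fan_out,
    mirnas = mirnas[c("mirna_id", "mirna_key", "mirbase_acc")],
    db_rows = rows,
    uniprot = uniprot,
    acc_table = acc_table
  )
}

#' Generate a ranked target list with planted enriched sets
#'
#' Builds a ranked list of `n` accessions with strictly positive, descending
#' rank values, plus a collection of target sets: `n_planted` sets whose
#' members are loaded into the top quantile of the list at the requested
#' fraction, and `n_null_sets` sets drawn uniformly. A loading fraction of 0
#' makes the "planted" sets indistinguishable from null sets (the calibration
#' fixture).
#'
#' @param n Length of the ranked list.
#' @param accessions Optional accession pool (length `>= n`); synthetic
#'   `T#####` accessions are generated otherwise.
#' @param n_planted Number of planted (enriched) sets.
#' @param planted_size Members per planted set.
#' @param loading_frac Fraction of each planted set's members placed in the
#'   top quantile.
#' @param top_quantile Which leading fraction of the list counts as "top".
#' @param n_null_sets Number of uniform null sets.
#' @param null_set_size Members per null set.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, `ranked.tsv` and
#'   `ranked_manifest.json` are written there.
#'
#' @return A list: `ranked` (tibble `accession`, `rank_value` in ranking
#'   order), `sets` (named list of accession vectors; planted sets are named
#'   `planted_#`, null sets `null_#`), and `manifest` (tibble `set`,
#'   `accession`, `position`, `in_top_quantile`).
#' @export
generate_ranked <- function(n = 200, accessions = NULL, n_planted = 1,
                            planted_size = 10, loading_frac = 1,
                            top_quantile = 0.1, n_null_sets = 20,
                            null_set_size = 10, seed = 1L, dir = NULL) {
  if (is.null(accessions)) accessions <- sprintf("T%05d", seq_len(n))
  stopifnot(length(accessions) >= n, loading_frac >= 0, loading_frac <= 1)
  n_top <- max(1L, floor(top_quantile * n))
  k_top <- round(loading_frac * planted_size)
  if (n_planted > 0 && k_top > n_top) {
    rlang::abort("Top quantile too small for the requested loading.")
  }

  out <- withr::with_seed(seed, {
    acc <- accessions[seq_len(n)]
    values <- sort(stats::runif(n, 0.5, 10), decreasing = TRUE)
    ranked <- tibble::tibble(accession = acc, rank_value = values)
    sets <- list()
    manifest <- list()
    for (i in seq_len(n_planted)) {
      top_pos <- if (k_top > 0) sample.int(n_top, k_top) else integer()
      rest_pos <- sample((n_top + 1L):n, planted_size - k_top)
      pos <- sort(c(top_pos, rest_pos))
      nm <- paste0("planted_", i)
      sets[[nm]] <- acc[pos]
      manifest[[nm]] <- tibble::tibble(set = nm, accession = acc[pos],
                                       position = pos,
                                       in_top_quantile = pos <= n_top)
    }
    for (i in seq_len(n_null_sets)) {
      pos <- sort(sample.int(n, null_set_size))
      nm <- paste0("null_", i)
      sets[[nm]] <- acc[pos]
      manifest[[nm]] <- tibble::tibble(set = nm, accession = acc[pos],
                                       position = pos,
                                       in_top_quantile = pos <= n_top)
    }
    list(ranked = ranked, sets = sets,
         manifest = dplyr::bind_rows(manifest))
  })

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(out$ranked, file.path(dir, "ranked.tsv"))
    jsonlite::write_json(
      list(sets = out$sets, manifest = out$manifest),
      file.path(dir, "ranked_manifest.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  }
  out
}
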