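MTI_DB_NAMES <- c("tarbase", "mirtarbase", "mirecords", "starbase")

MTI_DB_COLUMNS <- c("source_db", "mirna_id", "mirbase_acc", "target_symbol",
                    "species", "methods", "clip_support")

UNIPROT_COLUMNS <- c("accession", "gene_symbol", "synonyms", "species",
                     "protein_name", "go_terms", "cross_references")

#' Load one harmonized MTI source database
#'
#' Reads the tab-separated interchange format (one file per source database):
#' columns `source_db`, `mirna_id`, `mirbase_acc`, `target_symbol`, `species`,
#' `methods` (semicolon-joined), `clip_support`; `""` for absent. Rows that
#' violate the record invariants are rejected, counted and reported in the
#' `rejected` attribute — never fatal. A missing mandatory column aborts with
#' a schema error naming the column.
#'
#' CLIP-Seq support counts are only meaningful for starBase, so a positive
#' `clip_support` in any other database marks the row malformed.
#'
#' @param path Path to an interchange TSV.
#' @param source_db Which of the four databases this file holds
#'   (`"tarbase"`, `"mirtarbase"`, `"mirecords"`, `"starbase"`).
#'
#' @return A tibble of interaction records with `methods` as a list column of
#'   character vectors; `attr(, "rejected")` is a tibble (`row`, `reason`)
#'   describing dropped rows.
#' @export
read_mti_db <- function(path, source_db = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  missing_cols <- setdiff(MTI_DB_COLUMNS, names(tab))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("MTI interchange file '%s' lacks mandatory column(s): %s",
                         path, paste(missing_cols, collapse = ", ")))
  }
  tab <- tab[MTI_DB_COLUMNS]
  raw_clip <- stringr::str_trim(tab$clip_support)
  tab$clip_support <- suppressWarnings(as.integer(raw_clip))
  tab$clip_support[raw_clip == ""] <- 0L  # "" means absent, i.e. no CLIP data
  validate_mti_records(tab, source_db = source_db, path = path)
}

validate_mti_records <- function(tab, source_db = NULL, path = "<records>") {
  n <- nrow(tab)
  reason <- rep(NA_character_, n)
  flag <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }
  flag(!(tab$source_db %in% MTI_DB_NAMES), "unknown source_db")
  if (!is.null(source_db)) {
    flag(tab$source_db != source_db,
         sprintf("source_db differs from declared '%s'", source_db))
  }
  flag(is.na(tab$target_symbol) | tab$target_symbol == "", "empty target_symbol")
  flag(is.na(tab$species) | tab$species == "", "empty species")
  flag((is.na(tab$mirna_id) | tab$mirna_id == "") &
         (is.na(tab$mirbase_acc) | tab$mirbase_acc == ""),
       "neither mirna_id nor mirbase_acc")
  flag(is.na(tab$clip_support) | tab$clip_support < 0L, "bad clip_support")
  flag(tab$clip_support > 0L & tab$source_db != "starbase",
       "clip_support set outside starbase")

  bad <- !is.na(reason)
  rejected <- tibble::tibble(row = which(bad), reason = reason[bad])
  if (nrow(rejected) > 0) {
    rlang::inform(sprintf("%s: rejected %d malformed row(s) of %d.",
                          path, nrow(rejected), n))
  }
  out <- tibble::as_tibble(tab[!bad, ])
  out$methods <- stringr::str_split(out$methods, ";")
  out$methods <- purrr::map(out$methods,
                            function(m) stringr::str_trim(m[m != ""]))
  attr(out, "rejected") <- rejected
  out
}

#' Read the symbol-to-UniProt mapping table
#'
#' Tab-separated, one row per UniProt entry: `accession`, `gene_symbol`,
#' `synonyms` (semicolon-joined), `species`, `protein_name`, `go_terms`,
#' `cross_references`. Accessions must be unique.
#'
#' @param path Path to the mapping TSV.
#' @return A tibble with one row per accession.
#' @export
read_uniprot_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  missing_cols <- setdiff(UNIPROT_COLUMNS, names(tab))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("UniProt mapping file '%s' lacks column(s): %s",
                         path, paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(tab$accession)) {
    rlang::abort("UniProt mapping table has duplicated accessions.")
  }
  tibble::as_tibble(tab[UNIPROT_COLUMNS])
}

#' Read the miRBase accession table
#'
#' Two tab-separated columns: `accession`, `mirna_id`.
#'
#' @param path Path to the accession TSV.
#' @return A tibble mapping miRBase accessions to mature miRNA identifiers.
#' @export
read_accession_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  missing_cols <- setdiff(c("accession", "mirna_id"), names(tab))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("Accession table '%s' lacks column(s): %s",
                         path, paste(missing_cols, collapse = ", ")))
  }
  tibble::as_tibble(tab[c("accession", "mirna_id")])
}

#' Resolve miRBase accessions to miRNA identifiers
#'
#' TarBase-style records carry miRBase accessions instead of identifiers;
#' this fills `mirna_id` from the accession table. Records whose accession is
#' missing from the table (and that have no identifier of their own) are
#' dropped and counted — a drop-and-count policy, never an error.
#'
#' @param records MTI record tibble from [read_mti_db()].
#' @param acc_table Accession table from [read_accession_table()].
#'
#' @return The records with `mirna_id` filled; `attr(, "n_dropped")` counts
#'   unresolvable records.
#' @export
resolve_accessions <- function(records, acc_table) {
  lut <- stats::setNames(acc_table$mirna_id, acc_table$accession)
  needs <- is.na(records$mirna_id) | records$mirna_id == ""
  mapped <- unname(lut[records$mirbase_acc[needs]])
  records$mirna_id[needs] <- mapped
  drop <- is.na(records$mirna_id) | records$mirna_id == ""
  n_dropped <- sum(drop)
  if (n_dropped > 0) {
    rlang::inform(sprintf(
      "Dropped %d record(s) with unmappable miRBase accessions.", n_dropped))
  }
  out <- records[!drop, ]
  attr(out, "n_dropped") <- n_dropped
  attr(out, "rejected") <- attr(records, "rejected")
  out
}

# long lookup of every matchable token (symbol, synonym, cross-reference)
# per accession; token comparison is exact, case-insensitive
uniprot_token_index <- function(uniprot) {
  long <- tidyr::pivot_longer(
    uniprot[c("accession", "species", "gene_symbol", "synonyms",
              "cross_references")],
    cols = c("gene_symbol", "synonyms", "cross_references"),
    names_to = NULL, values_to = "token"
  )
  long <- tidyr::separate_rows(long, "token", sep = ";")
  long$token <- tolower(stringr::str_trim(long$token))
  dplyr::distinct(long[long$token != "", ])
}

#' Map target symbols to UniProt accessions
#'
#' A symbol matches a UniProt entry when it equals (case-insensitively) the
#' entry's gene symbol, any synonym, or any cross-reference — exact token
#' equality, no fuzzy matching. In species-specific mode only entries of the
#' query species are considered; in species-agnostic mode the species
#' constraint is dropped, which pulls in homologous targets across organisms.
#'
#' @param symbols Character vector of target symbols.
#' @param species Character vector of organism codes (recycled); ignored when
#'   `agnostic = TRUE`.
#' @param uniprot Mapping table from [read_uniprot_table()].
#' @param agnostic Ignore species membership?
#'
#' @return A tibble with one row per (query, matching accession):
#'   columns `symbol`, `query_species`, `accession`, `accession_species`.
#'   Symbols with no match contribute no rows.
#' @export
map_symbol_to_uniprot <- function(symbols, species = NA_character_,
                                  uniprot, agnostic = FALSE) {
  idx <- uniprot_token_index(uniprot)
  q <- tibble::tibble(
    symbol = symbols,
    query_species = rep_len(species, length(symbols)),
    token = tolower(stringr::str_trim(symbols))
  )
  hits <- dplyr::inner_join(q, idx, by = "token",
                            relationship = "many-to-many")
  if (!agnostic) {
    hits <- hits[hits$species == hits$query_species, ]
  }
  out <- dplyr::distinct(tibble::tibble(
    symbol = hits$symbol,
    query_species = hits$query_species,
    accession = hits$accession,
    accession_species = hits$species
  ))
  out
}

#' Harmonize MTI records into linked interactions
#'
#' Maps every record's target symbol to UniProt accessions (species-specific
#' or agnostic), parses and clusters the miRNA identifier under the active
#' policy, and pools the result into one linked interaction per
#' `(mirna_key, accession)` pair. Each pair carries a 4-bit occurrence string
#' over the source databases in the fixed order tarbase, mirtarbase,
#' mirecords, starbase ("1" = reported there), so cross-database agreement is
#' counted on harmonized accessions rather than raw symbols.
#'
#' Records whose symbol maps to no accession, or whose miRNA identifier does
#' not parse, are dropped and counted.
#'
#' @param records MTI record tibble (one or several databases row-bound), with
#'   accessions already resolved via [resolve_accessions()].
#' @param uniprot Mapping table from [read_uniprot_table()].
#' @param policy A [match_policy()] controlling the miRNA cluster keys.
#' @param agnostic Species-agnostic symbol mapping?
#'
#' @return A tibble of linked MTIs: `mirna_key`, `accession`, `species` (of
#'   the accession), `sources` (4-bit string), `n_dbs` (its popcount).
#'   Attributes: `n_unmapped` (records lost to symbol mapping),
#'   `n_unparsed` (records lost to identifier parsing), `n_events` (distinct
#'   (source_db, mirna_key, accession) mapping events, which equals
#'   `sum(n_dbs)`).
#' @export
harmonize_mtis <- function(records, uniprot, policy = match_policy(),
                           agnostic = FALSE) {
  if (nrow(records) == 0) {
    out <- tibble::tibble(mirna_key = character(), accession = character(),
                          species = character(), sources = character(),
                          n_dbs = integer())
    attr(out, "n_unmapped") <- 0L
    attr(out, "n_unparsed") <- 0L
    attr(out, "n_events") <- 0L
    return(out)
  }
  parsed <- suppressWarnings(parse_mirna_ids(records$mirna_id))
  ok <- !(records$mirna_id %in% attr(parsed, "skipped")$raw)
  n_unparsed <- sum(!ok)
  recs <- records[ok, ]
  recs$mirna_key <- cluster_key(parsed, policy)

  idx <- uniprot_token_index(uniprot)
  recs$token <- tolower(stringr::str_trim(recs$target_symbol))
  hits <- dplyr::inner_join(
    recs[c("source_db", "mirna_key", "token", "species")],
    idx, by = "token", suffix = c("", "_acc"),
    relationship = "many-to-many"
  )
  if (!agnostic) hits <- hits[hits$species_acc == hits$species, ]

  n_unmapped <- length(setdiff(
    paste(recs$source_db, recs$mirna_key, recs$token),
    paste(hits$source_db, hits$mirna_key, hits$token)
  ))
  if (n_unmapped > 0) {
    rlang::inform(sprintf(
      "%d record(s) had target symbols mapping to no UniProt accession.",
      n_unmapped))
  }

  events <- dplyr::distinct(
    tibble::tibble(source_db = hits$source_db, mirna_key = hits$mirna_key,
                   accession = hits$accession,
                   acc_species = hits$species_acc)
  )
  out <- events |>
    dplyr::group_by(.data$mirna_key, .data$accession) |>
    dplyr::summarise(
      species = dplyr::first(.data$acc_species),
      sources = occurrence_string(.data$source_db),
      .groups = "drop"
    )
  out$n_dbs <- popcount(out$sources)
  out <- dplyr::arrange(out, .data$mirna_key, .data$accession)
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_unparsed") <- n_unparsed
  attr(out, "n_events") <- nrow(events)
  out
}

# 4-bit presence string over the fixed database order
occurrence_string <- function(dbs) {
  paste(as.integer(MTI_DB_NAMES %in% dbs), collapse = "")
}

#' Number of set bits in an occurrence string
#'
#' @param sources Character vector of 4-bit occurrence strings.
#' @return Integer vector: how many source databases report each interaction.
#' @export
popcount <- function(sources) {
  as.integer(stringr::str_count(sources, "1"))
}
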