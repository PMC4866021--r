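#' MTI selection criteria
#'
#' The four user-adjustable stringency criteria applied to the pooled
#' reference databases: which source databases to use, in how many of them an
#' interaction must independently occur, the species of interest, the
#' accepted experimental validation methods, and — for starBase records only —
#' the minimal number of supporting CLIP-Seq experiments.
#'
#' @param selected_dbs Subset of `c("tarbase", "mirtarbase", "mirecords",
#'   "starbase")`.
#' @param min_db_occurrence Integer in `[1, 4]`; an interaction must be
#'   reported by at least this many of the selected databases. Cannot exceed
#'   the number of selected databases.
#' @param species Organism code (e.g. `"hsa"`) or `"any"`.
#' @param methods Character vector of accepted validation method labels, or
#'   `"all"`. Labels are free strings compared case-insensitively after
#'   trimming.
#' @param starbase_min_clip Positive integer; minimal CLIP-Seq support for
#'   starBase records. Other databases are unaffected.
#'
#' @return An object of class `filter_config`.
#' @examples
#' filter_config(species = "hsa", min_db_occurrence = 2)
#' @export
filter_config <- function(selected_dbs = MTI_DB_NAMES,
                          min_db_occurrence = 1L,
                          species = "any",
                          methods = "all",
                          starbase_min_clip = 1L) {
  selected_dbs <- match.arg(selected_dbs, MTI_DB_NAMES, several.ok = TRUE)
  min_db_occurrence <- as.integer(min_db_occurrence)
  starbase_min_clip <- as.integer(starbase_min_clip)
  if (min_db_occurrence < 1L || min_db_occurrence > 4L) {
    rlang::abort("`min_db_occurrence` must be in [1, 4].")
  }
  if (min_db_occurrence > length(selected_dbs)) {
    rlang::abort(sprintf(
      "`min_db_occurrence` (%d) exceeds the number of selected databases (%d).",
      min_db_occurrence, length(selected_dbs)))
  }
  if (starbase_min_clip < 1L) {
    rlang::abort("`starbase_min_clip` must be a positive integer.")
  }
  structure(
    list(selected_dbs = selected_dbs,
         min_db_occurrence = min_db_occurrence,
         species = species,
         methods = methods,
         starbase_min_clip = starbase_min_clip),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>",
      sprintf("  databases:         %s", paste(x$selected_dbs, collapse = ", ")),
      sprintf("  min DB occurrence: %d", x$min_db_occurrence),
      sprintf("  species:           %s", x$species),
      sprintf("  methods:           %s", paste(x$methods, collapse = ", ")),
      sprintf("  starBase min CLIP: %d", x$starbase_min_clip),
      sep = "\n")
  invisible(x)
}

#' Filter MTI records by database, species, method, and CLIP support
#'
#' Record-level selection (before UniProt harmonization): keeps records from
#' the selected source databases, of the configured species (or all), with at
#' least one accepted validation method, and — for starBase — with at least
#' `starbase_min_clip` supporting CLIP-Seq experiments. A pure subset
#' operation; an empty result only warns.
#'
#' @param records MTI record tibble from [read_mti_db()].
#' @param cfg A [filter_config()].
#' @return The surviving records.
#' @export
filter_records <- function(records, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  keep <- records$source_db %in% cfg$selected_dbs
  if (!identical(cfg$species, "any")) {
    keep <- keep & records$species == cfg$species
  }
  if (!identical(cfg$methods, "all")) {
    want <- tolower(stringr::str_trim(cfg$methods))
    keep <- keep & purrr::map_lgl(
      records$methods,
      function(m) length(intersect(tolower(stringr::str_trim(m)), want)) > 0
    )
  }
  keep <- keep & (records$source_db != "starbase" |
                    records$clip_support >= cfg$starbase_min_clip)
  out <- records[keep, ]
  if (nrow(out) == 0 && nrow(records) > 0) {
    rlang::warn("No MTI records survive the record-level filters.")
  }
  out
}

#' Filter linked MTIs by database occurrence
#'
#' Keeps `(mirna_key, accession)` pairs reported by at least
#' `min_db_occurrence` source databases (popcount of the occurrence string).
#'
#' @param linked Linked MTI tibble from [harmonize_mtis()].
#' @param cfg A [filter_config()].
#' @return The surviving linked MTIs.
#' @export
filter_occurrence <- function(linked, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  linked[popcount(linked$sources) >= cfg$min_db_occurrence, ]
}

#' Restrict linked MTIs to user-supplied miRNAs
#'
#' Keeps linked interactions whose miRNA key semantically matches any of the
#' user's identifiers under the active policy (shortened identifiers are
#' wildcards on their omitted parts). A `NULL` user list is a no-op — the use
#' cases that start from an annotation file alone pass no miRNA list.
#'
#' @param linked Linked MTI tibble.
#' @param user_ids Parsed identifier tibble from [parse_mirna_ids()] /
#'   [read_mirna_list()], or `NULL`.
#' @param policy The [match_policy()] the linked keys were built under.
#' @return The surviving linked MTIs.
#' @export
filter_by_user_mirnas <- function(linked, user_ids = NULL,
                                  policy = match_policy()) {
  if (is.null(user_ids)) return(linked)
  if (nrow(linked) == 0) return(linked)
  keys <- parse_mirna_ids(unique(linked$mirna_key))
  hit_key <- keys$raw[purrr::map_lgl(seq_len(nrow(keys)), function(i) {
    any(mirna_match(user_ids, keys[i, ], policy))
  })]
  out <- linked[linked$mirna_key %in% hit_key, ]
  if (nrow(out) == 0) {
    rlang::warn("No linked MTIs match the supplied miRNA list.")
  }
  out
}

#' Restrict linked MTIs to user-supplied target accessions
#'
#' Overlaps the linked interactions with the user's annotation file: keeps
#' pairs whose UniProt accession occurs in the user set. A `NULL` set is a
#' no-op (no annotation file submitted).
#'
#' @param linked Linked MTI tibble.
#' @param target_accessions Character vector of UniProt accessions, or `NULL`.
#' @return The surviving linked MTIs.
#' @export
filter_by_user_targets <- function(linked, target_accessions = NULL) {
  if (is.null(target_accessions)) return(linked)
  out <- linked[linked$accession %in% unique(target_accessions), ]
  if (nrow(out) == 0 && nrow(linked) > 0) {
    rlang::warn("No linked MTIs overlap the supplied target accessions.")
  }
  out
}

#' Read a target annotation file
#'
#' Tab-separated with a header; the UniProt accessions are taken from the
#' `accession` column (or the first column when no column is so named).
#' Accessions are deduplicated.
#'
#' @param path Path to the annotation TSV.
#' @return Character vector of unique accessions.
#' @export
read_target_file <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  col <- if ("accession" %in% names(tab)) "accession" else names(tab)[1]
  acc <- stringr::str_trim(tab[[col]])
  unique(acc[acc != ""])
}
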