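#' Assemble per-miRNA target sets
#'
#' Groups the filtered, linked interactions into one MTI set per miRNA key.
#' Sets may overlap: a target validated for several miRNAs appears in each of
#' their sets.
#'
#' @param linked Linked MTI tibble from [harmonize_mtis()] (post-filtering).
#' @return A tibble with one row per miRNA key: `mirna_key`, `n_targets`, and
#'   `targets`, a list column of per-target tibbles (`accession`, `sources`).
#' @export
build_mti_sets <- function(linked) {
  linked |>
    dplyr::group_by(.data$mirna_key) |>
    dplyr::summarise(
      n_targets = dplyr::n_distinct(.data$accession),
      targets = list(dplyr::pick("accession", "sources")),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_targets), .data$mirna_key)
}

#' MTI matrix of occurrence strings
#'
#' The full interaction relation as a matrix: rows are target accessions,
#' columns are miRNA keys, and each non-empty cell holds the interaction's
#' 4-bit database-occurrence string (order tarbase, mirtarbase, mirecords,
#' starbase). A cell is non-empty exactly when the pair is linked, so the
#' number of non-empty cells equals the number of linked MTIs.
#'
#' @param linked Linked MTI tibble.
#' @return A tibble: first column `accession`, then one column per miRNA key;
#'   empty string for absent interactions.
#' @export
build_mti_matrix <- function(linked) {
  if (nrow(linked) == 0) {
    return(tibble::tibble(accession = character()))
  }
  linked[c("accession", "mirna_key", "sources")] |>
    tidyr::pivot_wider(names_from = "mirna_key", values_from = "sources",
                       values_fill = "", names_sort = TRUE) |>
    dplyr::arrange(.data$accession)
}

#' MTI information table
#'
#' One row per target accession, aggregating all interacting miRNA keys and
#' joining the UniProt annotation (gene symbol, synonyms, species, protein
#' name, GO terms). An accession missing from the mapping table yields a row
#' with blank annotation and a warning (defensive; cannot happen when the
#' linked set was built from the same table).
#'
#' @param linked Linked MTI tibble.
#' @param uniprot Mapping table from [read_uniprot_table()].
#' @return A tibble with columns `accession`, `mirna_keys` (semicolon-joined),
#'   `n_mirnas`, `gene_symbol`, `synonyms`, `species`, `protein_name`,
#'   `go_terms`.
#' @export
build_info_table <- function(linked, uniprot) {
  info <- linked |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(
      mirna_keys = paste(sort(unique(.data$mirna_key)), collapse = ";"),
      n_mirnas = dplyr::n_distinct(.data$mirna_key),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      uniprot[c("accession", "gene_symbol", "synonyms", "species",
                "protein_name", "go_terms")],
      by = "accession"
    )
  unmapped <- is.na(info$gene_symbol)
  if (any(unmapped)) {
    rlang::warn(sprintf(
      "%d linked accession(s) absent from the mapping table; emitted blank.",
      sum(unmapped)))
    info[unmapped, c("gene_symbol", "synonyms", "species", "protein_name",
                     "go_terms")] <- ""
  }
  dplyr::arrange(info, .data$accession)
}

#' Pairwise target overlap between MTI sets
#'
#' Symmetric overlap matrix across all MTI sets — the numeric backing of the
#' set-overlap heatmap. The default metric is the Jaccard index
#' |A intersect B| / |A union B| (diagonal 1, entries in `[0, 1]`);
#' `"intersection-count"` gives raw shared-target counts. When an enrichment
#' analysis was run, pass its leading edges to compare only the core targets
#' that drive each set's score; a set with an empty leading edge gets a
#' zero row/column (diagonal excepted) and a warning.
#'
#' @param sets MTI set tibble from [build_mti_sets()].
#' @param leading_edges Optional named list (by `mirna_key`) of accession
#'   vectors substituted for the full sets.
#' @param metric `"jaccard"` or `"intersection-count"`.
#' @return A tibble: first column `mirna_key`, then one numeric column per
#'   set, in the same order.
#' @export
overlap_matrix <- function(sets, leading_edges = NULL, metric = "jaccard") {
  metric <- match.arg(metric, c("jaccard", "intersection-count"))
  stopifnot(nrow(sets) >= 1)
  members <- purrr::map(sets$targets, function(t) unique(t$accession))
  names(members) <- sets$mirna_key
  if (!is.null(leading_edges)) {
    members <- purrr::imap(members, function(m, key) {
      le <- leading_edges[[key]]
      if (is.null(le)) character() else intersect(m, le)
    })
    if (any(lengths(members) == 0)) {
      rlang::warn("Some sets have an empty leading edge; their overlaps are 0.")
    }
  }
  n <- length(members)
  mat <- matrix(0, n, n, dimnames = list(names(members), names(members)))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      inter <- length(intersect(members[[i]], members[[j]]))
      uni <- length(union(members[[i]], members[[j]]))
      v <- if (metric == "jaccard") {
        if (uni == 0) 0 else inter / uni
      } else {
        inter
      }
      mat[i, j] <- v
      mat[j, i] <- v
    }
  }
  if (metric == "jaccard") diag(mat) <- 1
  dplyr::bind_cols(tibble::tibble(mirna_key = rownames(mat)),
                   tibble::as_tibble(mat))
}

#' Per-stage miRNA and MTI counts
#'
#' The bar-graph table: how many distinct miRNAs and how many linked MTIs
#' survive each processing step, from raw input through parsing/deduplication,
#' database matching, the occurrence filter, and the target overlap. Stages
#' that do not apply (e.g. the miRNA input rows when no miRNA list was
#' supplied) are `NA`.
#'
#' @param n_input_raw,n_parsed_dedup Input-list sizes (or `NA`).
#' @param linked_matched,linked_occurrence,linked_overlap Linked MTI tibbles
#'   after miRNA matching, the occurrence filter, and the target overlap.
#' @return A tibble with columns `stage`, `n_mirnas`, `n_mtis`.
#' @export
step_counts <- function(n_input_raw = NA_integer_,
                        n_parsed_dedup = NA_integer_,
                        linked_matched, linked_occurrence, linked_overlap) {
  tibble::tibble(
    stage = c("input_mirnas_raw", "mirnas_parsed_dedup", "matched_in_dbs",
              "after_occurrence_filter", "after_target_overlap"),
    n_mirnas = c(n_input_raw, n_parsed_dedup,
                 dplyr::n_distinct(linked_matched$mirna_key),
                 dplyr::n_distinct(linked_occurrence$mirna_key),
                 dplyr::n_distinct(linked_overlap$mirna_key)),
    n_mtis = c(NA_integer_, NA_integer_,
               nrow(linked_matched), nrow(linked_occurrence),
               nrow(linked_overlap))
  )
}

#' Size-ranked MTI set table
#'
#' The ranking file used when no enrichment analysis is run: sets ordered by
#' descending number of targets, ties broken lexicographically by miRNA key.
#'
#' @param sets MTI set tibble from [build_mti_sets()].
#' @return A tibble `mirna_key`, `n_targets` in ranking order.
#' @export
rank_sets_by_size <- function(sets) {
  sets |>
    dplyr::arrange(dplyr::desc(.data$n_targets), .data$mirna_key) |>
    dplyr::select("mirna_key", "n_targets")
}
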