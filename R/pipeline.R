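#' Pipeline run configuration
#'
#' Bundles every input path and parameter of one pipeline run. The use case
#' is implied by which optional inputs are present: none (browse/filter the
#' databases), a miRNA list (per-miRNA target lists), a target annotation
#' file (relevant miRNAs), both (linked MTIs), and additionally a ranked
#' target file (set enrichment analysis — this requires the target file,
#' since the enrichment runs over the overlapped MTI sets).
#'
#' Contradictory configurations (e.g. `min_db_occurrence` larger than the
#' number of selected databases, which [filter_config()] rejects) abort
#' before any computation.
#'
#' @param db_paths Named character vector/list of interchange TSV paths; names
#'   must be among `c("tarbase", "mirtarbase", "mirecords", "starbase")`.
#' @param uniprot_path Symbol-to-UniProt mapping TSV.
#' @param acc_table_path miRBase accession TSV.
#' @param mirna_list Optional miRNA list file.
#' @param target_file Optional target annotation TSV.
#' @param ranked_file Optional ranked target TSV (enables the enrichment
#'   analysis; requires `target_file`).
#' @param filter A [filter_config()].
#' @param policy A [match_policy()].
#' @param agnostic Species-agnostic symbol mapping?
#' @param overlap_metric `"jaccard"` or `"intersection-count"` for the
#'   set-overlap matrix.
#' @param weight_p,n_perm,min_set_size Enrichment parameters (see
#'   [run_mtisea()]).
#' @param seed Integer seed for all randomness in the run.
#' @param out_dir Output directory.
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(db_paths, uniprot_path, acc_table_path,
                       mirna_list = NULL, target_file = NULL,
                       ranked_file = NULL,
                       filter = filter_config(), policy = match_policy(),
                       agnostic = FALSE, overlap_metric = "jaccard",
                       weight_p = 1, n_perm = 1000L, min_set_size = 3L,
                       seed = 1L, out_dir = tempfile("mirlink_run_")) {
  db_paths <- as.list(db_paths)
  if (length(db_paths) == 0 || !all(names(db_paths) %in% MTI_DB_NAMES)) {
    rlang::abort("`db_paths` must be named by the four source databases.")
  }
  missing <- !vapply(db_paths, file.exists, logical(1))
  if (any(missing)) {
    rlang::abort(sprintf("Reference database file(s) not found: %s",
                         paste(unlist(db_paths[missing]), collapse = ", ")))
  }
  if (!is.null(ranked_file) && is.null(target_file)) {
    rlang::abort("A ranked file requires a target annotation file.")
  }
  stopifnot(inherits(filter, "filter_config"), inherits(policy, "match_policy"))
  structure(
    list(db_paths = db_paths, uniprot_path = uniprot_path,
         acc_table_path = acc_table_path, mirna_list = mirna_list,
         target_file = target_file, ranked_file = ranked_file,
         filter = filter, policy = policy, agnostic = isTRUE(agnostic),
         overlap_metric = match.arg(overlap_metric,
                                    c("jaccard", "intersection-count")),
         weight_p = weight_p, n_perm = as.integer(n_perm),
         min_set_size = as.integer(min_set_size), seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full linkage pipeline
#'
#' Executes the configured use case end to end: loads and validates the
#' reference databases, resolves miRBase accessions, applies the record-level
#' filters, harmonizes target symbols to UniProt accessions, applies the
#' database-occurrence filter and the user miRNA/target restrictions, builds
#' the MTI sets, matrix, information table, overlap matrix and step counts,
#' and — when a ranked file is configured — the set enrichment analysis. All
#' result tables are written as TSVs into `out_dir` together with a JSON run
#' manifest (configuration, seed, package version, step counts); figures are
#' rendered from their TSV twins and a rendering failure only warns.
#'
#' @param config A [run_config()].
#' @return Invisibly, an object of class `mirlink_run` with components
#'   `linked` (final linked MTIs), `sets`, `matrix`, `info`, `overlap`,
#'   `counts`, `ranking`, `mtisea` (`NULL` without a ranked file), and
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  uniprot <- read_uniprot_table(config$uniprot_path)
  acc_table <- read_accession_table(config$acc_table_path)
  records <- dplyr::bind_rows(purrr::imap(
    config$db_paths,
    function(p, db) read_mti_db(p, source_db = db)
  ))
  records <- resolve_accessions(records, acc_table)

  user_ids <- NULL
  n_raw <- NA_integer_
  n_dedup <- NA_integer_
  if (!is.null(config$mirna_list)) {
    user_ids <- read_mirna_list(config$mirna_list)
    n_raw <- attr(user_ids, "n_raw")
    n_dedup <- dplyr::n_distinct(cluster_key(user_ids, config$policy))
  }
  target_acc <- if (is.null(config$target_file)) NULL else
    read_target_file(config$target_file)

  filtered <- filter_records(records, config$filter)
  linked_all <- harmonize_mtis(filtered, uniprot, policy = config$policy,
                               agnostic = config$agnostic)
  linked_matched <- filter_by_user_mirnas(linked_all, user_ids, config$policy)
  linked_occ <- filter_occurrence(linked_matched, config$filter)
  linked <- filter_by_user_targets(linked_occ, target_acc)

  counts <- step_counts(n_raw, n_dedup, linked_matched, linked_occ, linked)
  sets <- build_mti_sets(linked)
  mat <- build_mti_matrix(linked)
  info <- build_info_table(linked, uniprot)

  mtisea <- NULL
  leading_edges <- NULL
  ranking <- rank_sets_by_size(sets)
  if (!is.null(config$ranked_file) && nrow(sets) > 0) {
    ranked <- read_ranked_list(config$ranked_file)
    mtisea <- run_mtisea(sets, ranked, weight_p = config$weight_p,
                         n_perm = config$n_perm,
                         min_set_size = config$min_set_size,
                         seed = config$seed)
    if (nrow(mtisea$ranking) > 0) {
      leading_edges <- mtisea$leading_edges
      ranking <- mtisea$ranking
    }
  }
  overlap <- if (nrow(sets) > 0) {
    overlap_matrix(sets, leading_edges = leading_edges,
                   metric = config$overlap_metric)
  } else {
    tibble::tibble(mirna_key = character())
  }

  res <- structure(
    list(linked = linked, sets = sets, matrix = mat, info = info,
         overlap = overlap, counts = counts, ranking = ranking,
         mtisea = mtisea, config = config, out_dir = config$out_dir),
    class = "mirlink_run"
  )
  write_run_outputs(res)
  invisible(res)
}

#' @export
print.mirlink_run <- function(x, ...) {
  cat(sprintf(
    "<mirlink_run> %d linked MTIs, %d miRNA sets, %d target accessions\n",
    nrow(x$linked), nrow(x$sets), dplyr::n_distinct(x$linked$accession)))
  cat(sprintf("  outputs in %s\n", x$out_dir))
  invisible(x)
}

write_run_outputs <- function(res) {
  out <- res$out_dir
  readr::write_tsv(res$linked, file.path(out, "linked_mtis.tsv"))
  readr::write_tsv(res$matrix, file.path(out, "matrix.tsv"))
  readr::write_tsv(res$info, file.path(out, "info.tsv"))
  readr::write_tsv(res$overlap, file.path(out, "overlap_matrix.tsv"))
  readr::write_tsv(res$counts, file.path(out, "step_counts.tsv"))
  readr::write_tsv(res$ranking, file.path(out, "ranking.tsv"))
  if (!is.null(res$mtisea) && length(res$mtisea$traces) > 0) {
    tdir <- file.path(out, "traces")
    dir.create(tdir, showWarnings = FALSE)
    for (key in names(res$mtisea$traces)) {
      safe <- gsub("[^A-Za-z0-9._-]", "_", key)
      readr::write_tsv(res$mtisea$traces[[key]],
                       file.path(tdir, paste0("trace_", safe, ".tsv")))
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("mirlink")),
    seed = res$config$seed,
    agnostic = res$config$agnostic,
    filter = unclass(res$config$filter),
    policy = unclass(res$config$policy),
    weight_p = res$config$weight_p,
    n_perm = res$config$n_perm,
    min_set_size = res$config$min_set_size,
    inputs = list(mirna_list = res$config$mirna_list,
                  target_file = res$config$target_file,
                  ranked_file = res$config$ranked_file),
    step_counts = res$counts
  )
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       null = "null")
  render_figures(res)
  invisible(out)
}

# figure rendering never fails a run
render_figures <- function(res) {
  out <- res$out_dir
  try_plot <- function(p, name) {
    tryCatch(
      suppressMessages(ggplot2::ggsave(file.path(out, name), plot = p,
                                       width = 7, height = 5, dpi = 120)),
      error = function(e) {
        rlang::warn(sprintf("Could not render %s: %s", name,
                            conditionMessage(e)))
      }
    )
  }
  if (nrow(res$counts) > 0) {
    try_plot(plot_step_counts(res$counts), "step_counts.png")
  }
  if (nrow(res$overlap) > 1) {
    try_plot(plot_overlap_heatmap(res$overlap), "overlap_heatmap.png")
  }
  if (!is.null(res$mtisea) && nrow(res$mtisea$ranking) > 0) {
    top <- res$mtisea$ranking$mirna_key[1]
    safe <- gsub("[^A-Za-z0-9._-]", "_", top)
    try_plot(autoplot(res$mtisea, top),
             paste0("enrichment_", safe, ".png"))
  }
  invisible(NULL)
}
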