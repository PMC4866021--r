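# Figures are presentational twins of the tested TSV tables: each plot is
# drawn strictly from the corresponding table so the numbers, not the pixels,
# are the contract.

#' Enrichment plot for one MTI set
#'
#' The running enrichment score across the ranked list (curve), the positions
#' of the set's targets (rug), and the score extremum (vertical marker).
#'
#' @param object An `mtisea_result`.
#' @param mirna_key Which set to plot; default the top-ranked one.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mtisea_result
#' @export
autoplot.mtisea_result <- function(object, mirna_key = NULL, ...) {
  if (nrow(object$ranking) == 0) rlang::abort("Empty enrichment result.")
  if (is.null(mirna_key)) mirna_key <- object$ranking$mirna_key[1]
  if (!mirna_key %in% names(object$running_sums)) {
    rlang::abort(sprintf("No enrichment trace for set '%s'.", mirna_key))
  }
  rs <- object$running_sums[[mirna_key]]
  trace <- object$traces[[mirna_key]]
  row <- object$ranking[object$ranking$mirna_key == mirna_key, ]
  curve <- tibble::tibble(index = seq_along(rs), running_es = rs)

  ggplot2::ggplot(curve, ggplot2::aes(x = .data$index, y = .data$running_es)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = row$es_position, colour = "red",
                        linetype = "dashed") +
    ggplot2::geom_rug(data = trace, ggplot2::aes(x = .data$index),
                      sides = "b", inherit.aes = FALSE, colour = "black") +
    ggplot2::labs(
      title = sprintf("MTI set %s", mirna_key),
      subtitle = sprintf("ES = %.3f, NES = %.3f, FDR q = %.3f (n = %d)",
                         row$es, row$nes, row$fdr_q, row$set_size),
      x = "position in ranked target list", y = "running enrichment score"
    ) +
    ggplot2::theme_minimal()
}

#' Set-overlap heatmap
#'
#' Tile heatmap of the pairwise overlap matrix from [overlap_matrix()].
#'
#' @param overlap Overlap tibble (first column `mirna_key`).
#' @return A ggplot object.
#' @export
plot_overlap_heatmap <- function(overlap) {
  long <- tidyr::pivot_longer(overlap, cols = -"mirna_key",
                              names_to = "other", values_to = "overlap")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$other, y = .data$mirna_key,
                                     fill = .data$overlap)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, max(1, long$overlap))) +
    ggplot2::labs(x = NULL, y = NULL, fill = "overlap",
                  title = "MTI set target overlap") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Processing-step bar graph
#'
#' Side-by-side bars of the per-stage miRNA and MTI counts from
#' [step_counts()].
#'
#' @param counts Step-count tibble.
#' @return A ggplot object.
#' @export
plot_step_counts <- function(counts) {
  long <- tidyr::pivot_longer(counts, cols = c("n_mirnas", "n_mtis"),
                              names_to = "what", values_to = "n")
  long <- long[!is.na(long$n), ]
  long$stage <- factor(long$stage, levels = counts$stage)
  long$what <- factor(long$what, levels = c("n_mirnas", "n_mtis"),
                      labels = c("miRNAs", "MTIs"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "count",
                  title = "Counts after each processing step") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
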