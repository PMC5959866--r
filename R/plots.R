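
#' Rank plot of combined interaction p-values per bait
#'
#' Displays `-log10` combined p-values against within-bait rank, one
#' panel per bait, highlighting the selected (top-k) interactions — the
#' visual counterpart of the top-300 significance cut.
#'
#' @param object An `apms_scores` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.apms_scores <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$rank_within_bait,
                               y = -log10(.data$p_combined),
                               colour = .data$selected)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$bait_id)) +
    ggplot2::labs(x = "rank within bait", y = "-log10 combined p",
                  colour = "selected") +
    ggplot2::theme_minimal()
}

#' GFP depletion trajectories of a competitive-proliferation screen
#'
#' @param trajectories Trajectory tibble (schema of [simulate_screen()]).
#' @param genes Optional subset of gene identifiers to display.
#' @return A ggplot object: GFP% over time, one line per gene, faceted by
#'   cell line.
#' @export
plot_screen_trajectories <- function(trajectories, genes = NULL) {
  if (!is.null(genes)) {
    trajectories <- filter(trajectories, .data$gene_id %in% genes)
  }
  ggplot2::ggplot(trajectories,
                  ggplot2::aes(x = .data$timepoint_day,
                               y = .data$gfp_percent,
                               group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cell_line)) +
    ggplot2::labs(x = "day", y = "GFP-positive cells (%)") +
    ggplot2::theme_minimal()
}

#' Fusion-context vs wild-type depletion scatter
#'
#' Mirrors the counterscreen comparison: mean scaled depletion in
#' MLL-fusion-context lines against wild-type lines; fusion-selective
#' genes fall below the diagonal.
#'
#' @param selectivity_table Output of [selectivity()].
#' @return A ggplot object.
#' @export
plot_selectivity <- function(selectivity_table) {
  ggplot2::ggplot(selectivity_table,
                  ggplot2::aes(x = .data$mean_wt, y = .data$mean_fusion)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean depletion, MLL-wild-type lines",
                  y = "mean depletion, MLL-fusion lines") +
    ggplot2::theme_minimal()
}

#' Dual-signature fractions per gene set
#'
#' Bar chart of the fraction of genes carrying the joint high/high
#' histone-mark signature in each labelled gene set.
#'
#' @param calls A `signature_call` table.
#' @param gene_sets Named list of gene sets (e.g. MLL-target vs the
#'   remaining genes).
#' @return A ggplot object.
#' @export
plot_dual_signature <- function(calls, gene_sets) {
  df <- purrr::imap_dfr(gene_sets, function(gs, nm) {
    tibble(set = nm, fraction = dual_signature_fraction(calls, gs))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$fraction)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "dual-high genes") +
    ggplot2::theme_minimal()
}
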