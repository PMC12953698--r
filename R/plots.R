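#' Volcano plot of a differential-expression result
#'
#' @param object A `de_result` from [run_de_comparison()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), !is.na(.data$pvalue))
  ggplot2::ggplot(d, ggplot2::aes(.data$log2fc, -log10(.data$fdr),
                                  colour = .data$class)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(up = "#b386c6", down = "#4477aa",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a translational-efficiency result
#'
#' @param object A `te_result` from [run_te_analysis()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot te_result
#' @export
autoplot.te_result <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), !is.na(.data$pvalue))
  ggplot2::ggplot(d, ggplot2::aes(.data$delta_te_log2, -log10(.data$pvalue),
                                  colour = .data$class)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(te_up = "#b386c6",
                                            te_down = "#4477aa",
                                            ns = "grey70")) +
    ggplot2::labs(x = "delta TE (log2)", y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Meta-region heatmap
#'
#' Rows (regions, sorted by cluster then effect) by meta-bins, with flank
#' boundaries marked.
#'
#' @param object A `metaregion_matrix` from [tad_metaregion_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot metaregion_matrix
#' @export
autoplot.metaregion_matrix <- function(object, ...) {
  m <- object$matrix
  d <- tibble(row = rep(seq_len(nrow(m)), times = ncol(m)),
              bin = rep(seq_len(ncol(m)), each = nrow(m)),
              value = as.vector(m))
  edges <- c(object$flank_bins, object$flank_bins + object$body_bins) + 0.5
  ggplot2::ggplot(d, ggplot2::aes(.data$bin, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = edges, linetype = "dashed",
                        colour = "black") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#4477aa", mid = "white",
                                  high = "#cc3311") +
    ggplot2::labs(x = "meta-region bin", y = "region", fill = "signal") +
    ggplot2::theme_minimal()
}

#' Stage-profile violin plot
#'
#' TPM (log10 with a 1 pseudocount) of a gene cohort across the
#' stage-enriched libraries.
#'
#' @param table Stage-expression tibble (wide or long, see
#'   [fit_stage_nb_regression()]).
#' @param genes Optional gene ids to restrict to.
#' @return A ggplot.
#' @export
plot_stage_profiles <- function(table, genes = NULL) {
  long <- stage_table_long(table)
  if (!is.null(genes)) long <- dplyr::filter(long, .data$gene_id %in% genes)
  long$group <- factor(long$group,
                       levels = intersect(c("GSC", "CB", "cyst", "whole_ovary"),
                                          unique(long$group)))
  ggplot2::ggplot(long, ggplot2::aes(.data$group, log10(.data$tpm + 1))) +
    ggplot2::geom_violin(fill = "#b386c6", alpha = 0.6) +
    ggplot2::geom_boxplot(width = 0.1, outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = "log10(TPM + 1)") +
    ggplot2::theme_minimal()
}
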