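# ggplot2 displays for the main result types.

#' Volcano plot of an EWAS result
#'
#' Unadjusted exposed-minus-unexposed methylation difference against
#' -log10(p), with FDR and Bonferroni hits highlighted.
#'
#' @param object An `ewas_result`.
#' @param fdr_cutoff FDR threshold used for the colour scale.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ewas_result
#' @export
autoplot.ewas_result <- function(object, fdr_cutoff = 0.05, ...) {
  df <- as_tibble(object)
  df$significance <- dplyr::case_when(
    df$bonferroni_significant ~ "Bonferroni",
    df$q < fdr_cutoff ~ "FDR < 0.05",
    TRUE ~ "not significant")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$raw_difference,
                                   y = -log10(pmax(.data$p, 1e-300)),
                                   colour = .data$significance)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(
      "Bonferroni" = "#d73027", "FDR < 0.05" = "#fc8d59",
      "not significant" = "grey60")) +
    ggplot2::labs(x = "Methylation difference (exposed - unexposed)",
                  y = expression(-log[10](italic(p))), colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ewas_result
#' @param ewas An `ewas_result`.
#' @export
plot_volcano <- function(ewas, fdr_cutoff = 0.05) {
  autoplot.ewas_result(ewas, fdr_cutoff = fdr_cutoff)
}

#' Stacked bar chart of estimated cell-type proportions
#'
#' @param proportions A `cell_proportions` tibble.
#' @param group Optional vector (aligned with rows) used to facet, e.g. the
#'   exposure indicator.
#' @return A ggplot.
#' @export
plot_cell_proportions <- function(proportions, group = NULL) {
  df <- as_tibble(proportions)
  if (!is.null(group)) df$group <- factor(group)
  long <- tidyr::pivot_longer(df,
                              cols = -dplyr::any_of(c("sample_id", "group")),
                              names_to = "cell_type", values_to = "proportion")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                          y = .data$proportion,
                                          fill = .data$cell_type)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "Estimated proportion", fill = "Cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!is.null(group)) p <- p + ggplot2::facet_grid(~ group, scales = "free_x",
                                                    space = "free_x")
  p
}
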