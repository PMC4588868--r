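# broom-style views of the result tables.

#' Tidy an EWAS result into broom column conventions
#'
#' @param x An `ewas_result`.
#' @param ... Unused.
#' @return A tibble with `probe_id`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `q.value`.
#' @method tidy ewas_result
#' @export
tidy.ewas_result <- function(x, ...) {
  tibble(probe_id = x$probe_id, estimate = x$coefficient, std.error = x$se,
         statistic = x$t, p.value = x$p, q.value = x$q)
}

#' One-row summary of an EWAS result
#'
#' @param x An `ewas_result`.
#' @param fdr_cutoff FDR threshold for the hit count.
#' @param ... Unused.
#' @return A tibble: probe and sample counts, FDR and Bonferroni hit counts,
#'   and whether cell-type adjustment was applied.
#' @method glance ewas_result
#' @export
glance.ewas_result <- function(x, fdr_cutoff = 0.05, ...) {
  tibble(n_probes = nrow(x),
         n_samples = attr(x, "n_samples"),
         n_fdr_significant = sum(x$q < fdr_cutoff),
         n_bonferroni = sum(x$bonferroni_significant),
         cell_adjusted = isTRUE(attr(x, "cell_adjusted")))
}
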