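#' Select probes that discriminate between cell types
#'
#' Ranks probes by their between-cell-type variance in the reference signature
#' (the one-way F statistic across reference columns reduces to this spread
#' when the reference holds one mean profile per type) and returns the top
#' `k`. Ties are broken by row (probe id) order.
#'
#' @param reference A `meth_reference`.
#' @param k Number of probes to select.
#' @return Character vector of `k` probe ids, most discriminating first.
#' @export
#' @examples
#' ref <- simulate_reference(100, seed = 1)
#' head(select_discriminating_probes(ref, 10))
select_discriminating_probes <- function(reference, k) {
  stopifnot(inherits(reference, "meth_reference"))
  sig <- reference$signature
  k <- check_count(k, "k")
  if (k > nrow(sig)) {
    stop_invalid("`k` (%d) exceeds the number of reference probes (%d)",
                 k, nrow(sig))
  }
  v <- apply(sig, 1, var)
  ord <- order(-v, seq_along(v))   # stable: ties keep probe order
  rownames(sig)[ord[seq_len(k)]]
}

#' Estimate cell-type proportions by reference-based deconvolution
#'
#' Houseman-style constrained projection: for each sample, the beta values at
#' the selected discriminating probes are regressed on the reference signature
#' by nonnegative least squares (Lawson-Hanson active set). Only
#' nonnegativity is imposed — no sum-to-one equality — so the fitted
#' proportions may sum slightly away from 1; this keeps all cell types usable
#' simultaneously as regression covariates without exact collinearity with
#' the intercept. Set `renormalize = TRUE` to rescale each sample to sum 1.
#'
#' @param beta A probes x samples beta matrix or a `meth_cohort`.
#' @param reference A `meth_reference`.
#' @param probes Probe ids to use; defaults to the `min(100, n)` most
#'   discriminating reference probes.
#' @param renormalize Rescale each sample's proportions to sum to 1.
#' @return A tibble of class `cell_proportions`: `sample_id` plus one column
#'   per cell type.
#' @export
#' @examples
#' ref <- simulate_reference(60, seed = 1)
#' mix <- ref$signature %*% c(0.5, 0.5, 0, 0, 0, 0)
#' colnames(mix) <- "S1"
#' estimate_cell_proportions(mix, ref)
estimate_cell_proportions <- function(beta, reference, probes = NULL,
                                      renormalize = FALSE) {
  if (inherits(beta, "meth_cohort")) beta <- beta$beta
  stopifnot(is.matrix(beta), inherits(reference, "meth_reference"))
  sig <- reference$signature
  if (is.null(probes)) {
    probes <- select_discriminating_probes(reference, min(100L, nrow(sig)))
  }
  probes <- intersect(probes, rownames(beta))
  missing_ref <- setdiff(probes, rownames(sig))
  if (length(missing_ref) > 0) {
    stop_invalid("selected probes absent from the reference: %s",
                 paste(head(missing_ref, 5), collapse = ", "))
  }
  if (length(probes) < ncol(sig)) {
    stop_invalid("only %d selected probes remain in the beta matrix; need at least %d",
                 length(probes), ncol(sig))
  }
  S <- sig[probes, , drop = FALSE]
  qr_s <- qr(S)
  if (qr_s$rank < ncol(S)) {
    aliased <- colnames(S)[qr_s$pivot[(qr_s$rank + 1):ncol(S)]]
    stop_invalid("reference is rank deficient on the selected probes; collinear cell types: %s",
                 paste(aliased, collapse = ", "))
  }
  B <- beta[probes, , drop = FALSE]
  est <- vapply(seq_len(ncol(B)),
                function(j) pracma::lsqnonneg(S, B[, j])$x,
                numeric(ncol(S)))
  est <- t(est)
  colnames(est) <- colnames(S)
  if (renormalize) est <- est / rowSums(est)
  out <- tibble(sample_id = colnames(beta) %||% as.character(seq_len(ncol(beta))))
  out <- dplyr::bind_cols(out, as_tibble(est))
  class(out) <- c("cell_proportions", class(out))
  out
}
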