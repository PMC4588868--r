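# Fixed-effects inverse-variance pooling across cohorts.

#' Recover a standard error from an effect and a two-sided p-value
#'
#' `se = |effect| / qnorm(1 - p/2)`. This is how published cohort results that
#' print only effect and p-value can be pooled by inverse variance.
#'
#' @param effect Nonzero effect estimate(s).
#' @param p Two-sided p-value(s) strictly inside (0, 1).
#' @return Standard error(s).
#' @export
#' @examples
#' se_from_p(1.959964, 0.05)  # ~1
se_from_p <- function(effect, p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop_invalid("`p` must lie strictly inside (0, 1)")
  }
  if (any(effect == 0)) stop_invalid("`effect` must be nonzero")
  # upper-tail form keeps precision for very small p
  abs(effect) / qnorm(p / 2, lower.tail = FALSE)
}

resolve_se <- function(data) {
  se <- if ("se" %in% names(data)) data$se else rep(NA_real_, nrow(data))
  need <- !is.finite(se) | is.na(se)
  if (any(need)) {
    if (!"p" %in% names(data)) {
      stop_invalid("rows without `se` need a `p` column to recover it from")
    }
    se[need] <- se_from_p(data$effect[need], data$p[need])
  }
  if (any(se <= 0)) stop_invalid("all standard errors must be positive")
  se
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools per-cohort effects with weights `w_i = 1 / se_i^2`:
#' `pooled = sum(w_i e_i) / sum(w_i)`, `pooled_se = 1 / sqrt(sum(w_i))`,
#' `z = pooled / pooled_se` with a two-sided normal p-value. Rows lacking a
#' usable `se` have it recovered from their two-sided `p` via [se_from_p()].
#'
#' @param data Data frame with columns `effect` and at least one of `se`, `p`;
#'   an optional `cohort` column labels the weights.
#' @return A one-row tibble of class `meta_record`: `pooled_effect`,
#'   `pooled_se`, `z`, `p`, `k`; per-cohort weights in the `"weights"`
#'   attribute.
#' @export
#' @examples
#' fixed_effects_meta(tibble::tibble(
#'   cohort = c("discovery", "replication"),
#'   effect = c(-0.105, -0.103),
#'   p = c(2.67e-14, 2.30e-19)))
fixed_effects_meta <- function(data) {
  data <- as_tibble(data)
  if (nrow(data) < 1 || !"effect" %in% names(data)) {
    stop_invalid("`data` must have at least one row and an `effect` column")
  }
  se <- resolve_se(data)
  w <- 1 / se^2
  pooled <- sum(w * data$effect) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- pooled / pooled_se
  out <- tibble(pooled_effect = pooled, pooled_se = pooled_se,
                z = z, p = 2 * pnorm(-abs(z)), k = nrow(data))
  attr(out, "weights") <- setNames(w, data[["cohort"]] %||% paste0("cohort", seq_along(w)))
  class(out) <- c("meta_record", class(out))
  out
}

#' Meta-analysis of mediated effects with the replication decision rule
#'
#' Pools per-cohort indirect effects (`delta = beta_c - beta_c_prime`, grams)
#' by fixed-effects inverse variance, recovering standard errors from Sobel
#' p-values where needed. Computes the replication-only meta (rows whose
#' `stage` is `"replication"`) and the joint meta over all rows, and applies
#' the confirmation rule: mediation is confirmed when both are two-sided
#' significant at `alpha`.
#'
#' @param data Data frame with columns `cohort`, `effect` (the delta), `stage`
#'   (`"discovery"` or `"replication"`), and `se` and/or `p` (the Sobel p).
#' @param alpha Significance threshold for the confirmation rule.
#' @return One-row tibble: `replication_effect`, `replication_p`,
#'   `joint_effect`, `joint_se`, `joint_p`, `confirmed`, `k`.
#' @export
meta_mediation <- function(data, alpha = 0.05) {
  data <- as_tibble(data)
  if (!all(c("effect", "stage") %in% names(data))) {
    stop_invalid("`data` needs columns `effect` and `stage`")
  }
  if (!any(data$stage == "replication")) {
    stop_invalid("no replication-stage rows to pool")
  }
  repl <- fixed_effects_meta(data[data$stage == "replication", ])
  joint <- fixed_effects_meta(data)
  tibble(
    replication_effect = repl$pooled_effect,
    replication_p = repl$p,
    joint_effect = joint$pooled_effect,
    joint_se = joint$pooled_se,
    joint_p = joint$p,
    confirmed = repl$p < alpha & joint$p < alpha,
    k = nrow(data)
  )
}

#' Mediated fraction of the pooled total effect
#'
#' @param pooled_delta Pooled indirect effect (grams).
#' @param pooled_total_effect Pooled total exposure effect (grams), nonzero.
#' @return The ratio, as a proportion.
#' @export
#' @examples
#' mediation_fraction_of_total(-37.5, -202)  # ~0.186
mediation_fraction_of_total <- function(pooled_delta, pooled_total_effect) {
  if (any(pooled_total_effect == 0)) {
    stop_invalid("`pooled_total_effect` must be nonzero")
  }
  pooled_delta / pooled_total_effect
}

#' @export
print.meta_record <- function(x, ...) {
  cat(sprintf("<meta_record> pooled %.4g (se %.3g), z = %.2f, p = %.3g, k = %d\n",
              x$pooled_effect, x$pooled_se, x$z, x$p, x$k))
  invisible(x)
}
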