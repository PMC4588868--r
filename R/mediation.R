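# Baron-Kenny mediation of the exposure -> birthweight effect through a CpG.

#' Sobel test of an indirect effect
#'
#' `z = (beta_a * beta_b) / sqrt(beta_a^2 * se_b^2 + beta_b^2 * se_a^2)` with
#' a two-sided p-value from the standard normal. Because the three mediation
#' models are nested linear models on the same samples, `beta_a * beta_b`
#' equals `beta_c - beta_c_prime`, so this is equivalently a test of the drop
#' in the exposure coefficient.
#'
#' @param beta_a,se_a Exposure -> mediator coefficient and its SE.
#' @param beta_b,se_b Mediator -> outcome coefficient (adjusted for exposure)
#'   and its SE.
#' @return A tibble with columns `z` and `p` (vectorised over the inputs).
#' @export
#' @examples
#' sobel_test(1, 0, 2, 1)   # z = 2, p ~ 0.0455
sobel_test <- function(beta_a, se_a, beta_b, se_b) {
  if (any(se_a < 0) || any(se_b < 0)) stop_invalid("standard errors must be nonnegative")
  if (any(se_a == 0 & se_b == 0)) {
    stop_invalid("at least one of `se_a`, `se_b` must be positive")
  }
  se <- sqrt(beta_a^2 * se_b^2 + beta_b^2 * se_a^2)
  z <- ifelse(se > 0, (beta_a * beta_b) / se, 0)
  tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Proportion of the total effect explained by mediation
#'
#' Product form `(beta_a * beta_b) / (beta_a * beta_b + beta_c_prime)`; under
#' the OLS identity `beta_a * beta_b = beta_c - beta_c_prime` this equals
#' `(beta_c - beta_c_prime) / beta_c`. When the implied total effect is within
#' `tol` of zero the estimate is numerically unstable and is flagged with a
#' warning.
#'
#' @param beta_a,beta_b,beta_c_prime Coefficients as in [sobel_test()] plus
#'   the direct (mediator-adjusted) exposure -> outcome effect.
#' @param tol Instability threshold on the denominator.
#' @return Numeric proportion(s) of the total effect that is mediated.
#' @export
#' @examples
#' mediation_percentage(1, -121.0, -143.3)  # 0.458, as a proportion
mediation_percentage <- function(beta_a, beta_b, beta_c_prime, tol = 1e-8) {
  ab <- beta_a * beta_b
  denom <- ab + beta_c_prime
  unstable <- abs(denom) < tol
  if (any(unstable)) {
    rlang::warn("total effect within tolerance of zero; mediation percentage is unstable")
  }
  ifelse(ab == 0, 0, ab / denom)
}

# Assemble the complete-case analysis frame for one probe.
mediation_frame <- function(cohort, proportions, probe_id, covariates) {
  samples <- as_tibble(cohort$samples)
  if (!probe_id %in% rownames(cohort$beta)) {
    stop_invalid("probe '%s' not present in the beta matrix", probe_id)
  }
  df <- samples[, c("sample_id", "birthweight", "exposure", covariates),
                drop = FALSE]
  df$cpg <- cohort$beta[probe_id, samples$sample_id]
  if (!is.null(proportions)) {
    props <- as_tibble(proportions)
    idx <- match(samples$sample_id, props$sample_id)
    if (anyNA(idx)) stop_invalid("cell proportions missing for some samples")
    df <- dplyr::bind_cols(df, props[idx, setdiff(names(props), "sample_id"),
                                     drop = FALSE])
  }
  for (nm in names(df)) {
    if (is.character(df[[nm]]) && nm != "sample_id") df[[nm]] <- factor(df[[nm]])
  }
  df <- df[complete.cases(df), , drop = FALSE]
  if (var(df$cpg) == 0) {
    stop_invalid("probe '%s' has zero variance across samples", probe_id)
  }
  df
}

coef_row <- function(fit, term) {
  sm <- summary(fit)$coefficients
  c(estimate = sm[term, "Estimate"], se = sm[term, "Std. Error"],
    p = sm[term, "Pr(>|t|)"])
}

#' Fit the Baron-Kenny mediation models for one probe
#'
#' Fits, on one identical complete-case sample set, (a) `cpg ~ exposure +
#' covariates`, (c) `birthweight ~ exposure + covariates` and the full model
#' `birthweight ~ exposure + cpg + covariates`, and derives the indirect
#' effect `delta = beta_c - beta_c_prime` (equal to `beta_a * beta_b` by the
#' nested-OLS identity, which is asserted to relative tolerance 1e-8 on every
#' call), the mediation percentage, the Sobel z and p, and the Baron-Kenny
#' condition flags.
#'
#' @param cohort A QC'd `meth_cohort`.
#' @param proportions Optional `cell_proportions` used as extra covariates.
#' @param probe_id Single probe id.
#' @param covariates Sample-sheet covariates (paternal smoking is included
#'   automatically when present, the replication-cohort convention).
#' @param alpha Significance level for the condition flags.
#' @return An object of class `mediation_fit`: list with `record` (one-row
#'   tibble, see [run_mediation()]) and `models` (the three `lm` fits).
#' @export
fit_mediation <- function(cohort, proportions = NULL, probe_id,
                          covariates = ewas_covariates(), alpha = 0.05) {
  if ("paternal_smoking" %in% names(cohort$samples) &&
      !"paternal_smoking" %in% covariates &&
      var(cohort$samples$paternal_smoking, na.rm = TRUE) > 0) {
    covariates <- c(covariates, "paternal_smoking")
  }
  df <- mediation_frame(cohort, proportions, probe_id, covariates)
  rhs_cov <- setdiff(names(df), c("sample_id", "birthweight", "exposure", "cpg"))
  form <- function(lhs, extra = character()) {
    as.formula(paste(lhs, "~", paste(c("exposure", extra, rhs_cov), collapse = " + ")))
  }
  m_a <- lm(form("cpg"), data = df)
  m_c <- lm(form("birthweight"), data = df)
  m_full <- lm(form("birthweight", "cpg"), data = df)

  a <- coef_row(m_a, "exposure")
  cc <- coef_row(m_c, "exposure")
  cp <- coef_row(m_full, "exposure")
  b <- coef_row(m_full, "cpg")

  delta <- cc[["estimate"]] - cp[["estimate"]]
  ab <- a[["estimate"]] * b[["estimate"]]
  if (abs(ab - delta) > 1e-8 * max(1, abs(cc[["estimate"]]))) {
    rlang::abort(sprintf(
      "OLS mediation identity violated (beta_a*beta_b = %.10g vs delta = %.10g); the three models were not fitted on identical samples",
      ab, delta), class = "methmediate_identity_error")
  }
  sob <- sobel_test(a[["estimate"]], a[["se"]], b[["estimate"]], b[["se"]])
  pct <- mediation_percentage(a[["estimate"]], b[["estimate"]], cp[["estimate"]])

  record <- tibble(
    probe_id = probe_id,
    beta_a = a[["estimate"]], se_a = a[["se"]], p_a = a[["p"]],
    beta_c = cc[["estimate"]], se_c = cc[["se"]], p_c = cc[["p"]],
    beta_c_prime = cp[["estimate"]], se_c_prime = cp[["se"]],
    beta_b = b[["estimate"]], se_b = b[["se"]], p_b = b[["p"]],
    delta = delta,
    se_delta = sqrt(a[["estimate"]]^2 * b[["se"]]^2 +
                      b[["estimate"]]^2 * a[["se"]]^2),
    mediation_pct = 100 * pct,
    sobel_z = sob$z, sobel_p = sob$p,
    r_square_c = summary(m_c)$r.squared,
    cond_exposure_mediator = a[["p"]] < alpha,
    cond_total_effect = cc[["p"]] < alpha,
    cond_mediator_outcome = b[["p"]] < alpha,
    cond_effect_drop = abs(cp[["estimate"]]) < abs(cc[["estimate"]]),
    n_used = nrow(df)
  )
  structure(list(record = record,
                 models = list(mediator = m_a, total = m_c, full = m_full),
                 probe_id = probe_id),
            class = "mediation_fit")
}

#' Mediation analysis over a set of probes
#'
#' Runs [fit_mediation()] for each probe and stacks the one-row records.
#' `mediation_pct` is reported as a percentage; `delta` (grams) is the
#' indirect effect `beta_c - beta_c_prime`. All rows are reported regardless
#' of whether the Baron-Kenny conditions hold; the condition flags say which
#' do.
#'
#' @inheritParams fit_mediation
#' @param probe_ids Character vector of probes to test.
#' @return A tibble of class `mediation_result`, one row per probe.
#' @export
run_mediation <- function(cohort, proportions = NULL, probe_ids,
                          covariates = ewas_covariates(), alpha = 0.05) {
  out <- purrr::map_dfr(probe_ids, function(pb) {
    fit_mediation(cohort, proportions, pb, covariates, alpha)$record
  })
  class(out) <- c("mediation_result", class(out))
  out
}

#' Check the no-interaction assumption of the mediation model
#'
#' Augments the full mediation model with an exposure-by-mediator interaction
#' and, one at a time, each covariate-by-mediator interaction, reporting the
#' interaction coefficient, SE and p-value for each.
#'
#' @inheritParams fit_mediation
#' @return A tibble: `term`, `estimate`, `se`, `statistic`, `p_value`.
#' @export
interaction_check <- function(cohort, proportions = NULL, probe_id,
                              covariates = ewas_covariates()) {
  df <- mediation_frame(cohort, proportions, probe_id, covariates)
  rhs_cov <- setdiff(names(df), c("sample_id", "birthweight", "exposure", "cpg"))
  base <- paste(c("exposure", "cpg", rhs_cov), collapse = " + ")
  purrr::map_dfr(c("exposure", rhs_cov), function(v) {
    f <- as.formula(paste("birthweight ~", base, "+", v, ":cpg"))
    fit <- lm(f, data = df)
    sm <- summary(fit)$coefficients
    hit <- grep(":", rownames(sm), value = TRUE)
    tibble(term = hit,
           estimate = sm[hit, "Estimate"],
           se = sm[hit, "Std. Error"],
           statistic = sm[hit, "t value"],
           p_value = sm[hit, "Pr(>|t|)"])
  })
}

#' @export
print.mediation_fit <- function(x, ...) {
  r <- x$record
  cat(sprintf("<mediation_fit> probe %s (n = %d)\n", x$probe_id, r$n_used))
  cat(sprintf("  beta_c = %.1f, beta_c' = %.1f, delta = %.1f g (%.1f%% mediated)\n",
              r$beta_c, r$beta_c_prime, r$delta, r$mediation_pct))
  cat(sprintf("  Sobel z = %.2f, p = %.3g\n", r$sobel_z, r$sobel_p))
  invisible(x)
}

#' @method tidy mediation_fit
#' @export
tidy.mediation_fit <- function(x, ...) {
  purrr::map_dfr(names(x$models), function(nm) {
    sm <- summary(x$models[[nm]])$coefficients
    tibble(model = nm, term = rownames(sm),
           estimate = sm[, "Estimate"], std.error = sm[, "Std. Error"],
           statistic = sm[, "t value"], p.value = sm[, "Pr(>|t|)"])
  })
}

#' @method glance mediation_fit
#' @export
glance.mediation_fit <- function(x, ...) {
  r <- x$record
  tibble(probe_id = r$probe_id, delta = r$delta,
         mediation_pct = r$mediation_pct, sobel_z = r$sobel_z,
         sobel_p = r$sobel_p, r_square_c = r$r_square_c, n = r$n_used)
}
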