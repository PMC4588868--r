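# Covariate-adjusted per-CpG linear modelling.

#' Default EWAS covariate set
#' @export
ewas_covariates <- function() {
  c("sex", "gestational_age", "maternal_age", "maternal_bmi", "education", "plate")
}

# Build the n x k numeric design matrix: intercept, optional exposure (or
# another focal regressor), covariates (factors/character expanded to
# treatment dummies), and cell-type proportion columns.
build_design <- function(samples, proportions = NULL,
                         covariates = ewas_covariates(),
                         focal = "exposure") {
  samples <- as_tibble(samples)
  missing_cov <- setdiff(c(focal, covariates), names(samples))
  if (length(missing_cov) > 0) {
    stop_invalid("sample sheet lacks columns: %s",
                 paste(missing_cov, collapse = ", "))
  }
  df <- samples[, c(focal, covariates), drop = FALSE]
  if (anyNA(df)) {
    bad <- names(df)[vapply(df, anyNA, logical(1))]
    stop_invalid("missing values in model variables (%s); run impute_covariates() first",
                 paste(bad, collapse = ", "))
  }
  for (nm in names(df)) {
    if (is.character(df[[nm]]) || is.factor(df[[nm]])) {
      if (length(unique(df[[nm]])) < 2) {
        stop_invalid("covariate '%s' has a single level", nm)
      }
      df[[nm]] <- factor(df[[nm]])
    }
  }
  X <- model.matrix(~ ., data = df)
  if (!is.null(proportions)) {
    props <- as_tibble(proportions)
    idx <- match(samples$sample_id, props$sample_id)
    if (anyNA(idx)) {
      stop_invalid("cell proportions missing for samples: %s",
                   paste(head(samples$sample_id[is.na(idx)], 5), collapse = ", "))
    }
    pm <- as.matrix(props[idx, setdiff(names(props), "sample_id"), drop = FALSE])
    X <- cbind(X, pm)
  }
  rownames(X) <- samples$sample_id
  X
}

check_full_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_invalid("design is rank deficient; aliased columns: %s",
                 paste(aliased, collapse = ", "))
  }
  qx
}

# Shared OLS core: one QR of the design serves every probe (the standard
# many-outcomes shortcut). Returns coefficient, se, t, p for `column`.
ols_by_probe <- function(X, Y, column) {
  n <- nrow(X); k <- ncol(X)
  if (n <= k) stop_invalid("need more samples (%d) than parameters (%d)", n, k)
  qx <- check_full_rank(X)
  cf <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  df <- n - k
  sigma2 <- colSums(res^2) / df
  vjj <- chol2inv(qr.R(qx))[qx$pivot == which(colnames(X) == column),
                            qx$pivot == which(colnames(X) == column)]
  se <- unname(sqrt(sigma2 * vjj))
  est <- unname(cf[column, ])
  tval <- ifelse(se > 0, est / se, ifelse(est == 0, 0, sign(est) * Inf))
  p <- 2 * pt(-abs(tval), df)
  p[se == 0 & est != 0] <- 0      # exact fit: zero residual variance
  p[se == 0 & est == 0] <- 1
  tibble(coefficient = est, se = se, t = tval, p = p, n_used = n)
}

#' Fit the per-probe exposure model for a single probe
#'
#' Ordinary least squares of one probe's beta values on exposure plus
#' covariates, reporting the exposure coefficient with its Student-t two-sided
#' p-value (n - k residual degrees of freedom). With no covariates the
#' coefficient is exactly the difference of group means.
#'
#' @param y Numeric vector of per-sample beta values.
#' @param exposure Binary (0/1) exposure vector.
#' @param covariates Optional data frame of covariates aligned with `y`.
#' @return One-row tibble: `coefficient`, `se`, `t`, `p`, `n_used`.
#' @export
#' @examples
#' fit_probe_model(c(0.5, 0.6, 0.7, 0.8), exposure = c(0, 0, 1, 1))
fit_probe_model <- function(y, exposure, covariates = NULL) {
  if (!is.numeric(y) || length(y) != length(exposure)) {
    stop_invalid("`y` and `exposure` must be numeric vectors of equal length")
  }
  df <- tibble(exposure = as.numeric(exposure))
  if (!is.null(covariates)) {
    covariates <- as_tibble(covariates)
    for (nm in names(covariates)) {
      if (is.character(covariates[[nm]])) covariates[[nm]] <- factor(covariates[[nm]])
    }
    df <- dplyr::bind_cols(df, covariates)
  }
  fit <- lm(y ~ ., data = df)
  qx <- qr(model.matrix(fit))
  if (qx$rank < ncol(model.matrix(fit))) {
    aliased <- colnames(model.matrix(fit))[qx$pivot[(qx$rank + 1):ncol(model.matrix(fit))]]
    stop_invalid("design is rank deficient; aliased columns: %s",
                 paste(aliased, collapse = ", "))
  }
  sm <- suppressWarnings(summary(fit))   # silence the perfect-fit warning
  est <- sm$coefficients["exposure", "Estimate"]
  se <- sm$coefficients["exposure", "Std. Error"]
  if (sm$sigma < .Machine$double.eps^0.5) {
    # zero-residual degenerate fit: treat as exact
    se <- 0
    p <- if (est == 0) 1 else 0
    tval <- if (est == 0) 0 else sign(est) * Inf
  } else {
    tval <- sm$coefficients["exposure", "t value"]
    p <- sm$coefficients["exposure", "Pr(>|t|)"]
  }
  tibble(coefficient = est, se = se, t = tval, p = p,
         n_used = length(fit$residuals))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment: `q_i` is the smallest value of `m * p_(j) / j` over
#' all `j` whose ordered p-value is at least `p_(i)`, capped at 1 and mapped
#' back to input order (delegates to [stats::p.adjust()] after validating the
#' input).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order as `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p) {
  if (length(p) == 0 || anyNA(p) || !is.numeric(p) || min(p) < 0 || max(p) > 1) {
    stop_invalid("`p` must be a non-empty numeric vector with values in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Run the epigenome-wide association analysis
#'
#' Fits, for every probe, an ordinary least squares model of methylation beta
#' on exposure plus covariates (plate as dummy-coded categorical) and,
#' optionally, the estimated cell-type proportions. Reports the exposure
#' coefficient, its Student-t two-sided p-value, BH-FDR q-values over all
#' tested probes, a Bonferroni significance flag, the unadjusted
#' exposed-minus-unexposed difference of mean betas, and the overall mean
#' methylation.
#'
#' @param cohort A `meth_cohort` that has already been through QC and
#'   imputation.
#' @param proportions A `cell_proportions` table, or `NULL` to omit cell-type
#'   adjustment (sensitivity mode).
#' @param covariates Character vector of sample-sheet covariates; use
#'   `character()` for the crude model.
#' @param bonferroni Either `"genomewide"` (fixed threshold `p <
#'   genomewide_threshold`, the 450K convention) or `"exact"` (`p < 0.05 / m`
#'   over the `m` probes tested) for the `bonferroni_significant` flag; the
#'   other convention is also returned as its own column.
#' @param genomewide_threshold Fixed genome-wide threshold (default `1e-7`).
#' @return A tibble of class `ewas_result`, one row per probe: `probe_id`,
#'   `coefficient`, `se`, `t`, `p`, `q`, `bonferroni_significant`,
#'   `bonferroni_exact`, `mean_methylation`, `raw_difference`, `n_used`.
#' @export
run_ewas <- function(cohort, proportions = NULL,
                     covariates = ewas_covariates(),
                     bonferroni = c("genomewide", "exact"),
                     genomewide_threshold = 1e-7) {
  stopifnot(is.list(cohort), is.matrix(cohort$beta))
  bonferroni <- match.arg(bonferroni)
  samples <- as_tibble(cohort$samples)
  X <- build_design(samples, proportions, covariates, focal = "exposure")
  Y <- t(cohort$beta[, samples$sample_id, drop = FALSE])
  res <- ols_by_probe(X, Y, "exposure")

  m <- nrow(cohort$beta)
  exposed <- samples$sample_id[samples$exposure == 1]
  unexposed <- samples$sample_id[samples$exposure == 0]
  raw_diff <- rowMeans(cohort$beta[, exposed, drop = FALSE]) -
    rowMeans(cohort$beta[, unexposed, drop = FALSE])

  out <- tibble(
    probe_id = rownames(cohort$beta),
    coefficient = res$coefficient,
    se = res$se,
    t = res$t,
    p = res$p,
    q = bh_fdr(res$p),
    bonferroni_exact = res$p < 0.05 / m,
    genomewide = res$p < genomewide_threshold,
    mean_methylation = rowMeans(cohort$beta),
    raw_difference = raw_diff,
    n_used = res$n_used
  )
  out$bonferroni_significant <- if (bonferroni == "genomewide") out$genomewide
                                else out$bonferroni_exact
  out <- out[, c("probe_id", "coefficient", "se", "t", "p", "q",
                 "bonferroni_significant", "bonferroni_exact",
                 "mean_methylation", "raw_difference", "n_used")]
  attr(out, "n_samples") <- nrow(samples)
  attr(out, "covariates") <- covariates
  attr(out, "cell_adjusted") <- !is.null(proportions)
  attr(out, "bonferroni") <- bonferroni
  attr(out, "genomewide_threshold") <- genomewide_threshold
  class(out) <- c("ewas_result", class(out))
  out
}

#' Dose-response test within the exposed group
#'
#' Regresses each probe's methylation on cigarettes smoked per day plus
#' covariates, using exposed samples only.
#'
#' @param cohort A QC'd `meth_cohort`.
#' @param proportions Optional `cell_proportions`.
#' @param probe_ids Probes to test (e.g. the FDR hits of [run_ewas()]).
#' @param covariates Sample-sheet covariates to adjust for.
#' @return A tibble: `probe_id`, `slope` (beta per cigarette/day), `se`, `t`,
#'   `p`, `n_used`, `low_n` flag (set with a warning when fewer than 10
#'   exposed samples are available).
#' @export
dose_response_test <- function(cohort, proportions = NULL, probe_ids = NULL,
                               covariates = ewas_covariates()) {
  samples <- as_tibble(cohort$samples)
  samples <- samples[samples$exposure == 1, , drop = FALSE]
  if (nrow(samples) == 0) stop_invalid("no exposed samples")
  if (!"cigarettes_per_day" %in% names(samples) ||
      anyNA(samples$cigarettes_per_day)) {
    stop_invalid("`cigarettes_per_day` must be present and complete for exposed samples")
  }
  if (var(samples$cigarettes_per_day) == 0) {
    stop_invalid("`cigarettes_per_day` has zero variance among exposed samples")
  }
  low_n <- nrow(samples) < 10
  if (low_n) {
    rlang::warn(sprintf("only %d exposed samples; dose-response estimates flagged low-n",
                        nrow(samples)))
  }
  probe_ids <- probe_ids %||% rownames(cohort$beta)
  X <- build_design(samples, proportions, covariates, focal = "cigarettes_per_day")
  Y <- t(cohort$beta[probe_ids, samples$sample_id, drop = FALSE])
  res <- ols_by_probe(X, Y, "cigarettes_per_day")
  tibble(probe_id = probe_ids, slope = res$coefficient, se = res$se,
         t = res$t, p = res$p, n_used = res$n_used, low_n = low_n)
}

#' Cohort descriptives with between-group tests
#'
#' Group-wise mean (SD) with equal-variance two-sample t-tests for continuous
#' variables, and count (%) with chi-square tests for categorical variables.
#' The reported `difference` is exposed minus unexposed (mean difference for
#' continuous variables, difference in percentage for categorical ones).
#'
#' @param samples Sample sheet with an `exposure` column.
#' @param continuous,categorical Variable names to summarise.
#' @return A tibble: `variable`, `type`, `unexposed`, `exposed` (formatted
#'   summaries), `mean_unexposed`, `mean_exposed`, `difference`, `p_value`.
#' @export
descriptive_table <- function(samples,
                              continuous = c("birthweight", "gestational_age",
                                             "maternal_age", "maternal_bmi"),
                              categorical = c("sex", "education")) {
  samples <- as_tibble(samples)
  g0 <- samples[samples$exposure == 0, , drop = FALSE]
  g1 <- samples[samples$exposure == 1, , drop = FALSE]
  if (nrow(g0) == 0 || nrow(g1) == 0) stop_invalid("both exposure groups must be non-empty")

  cont <- purrr::map_dfr(intersect(continuous, names(samples)), function(v) {
    x0 <- g0[[v]]; x1 <- g1[[v]]
    pv <- if (sd(c(x0, x1), na.rm = TRUE) == 0) 1
          else t.test(x1, x0, var.equal = TRUE)$p.value
    tibble(variable = v, type = "continuous",
           unexposed = sprintf("%.1f ± %.1f", mean(x0, na.rm = TRUE), sd(x0, na.rm = TRUE)),
           exposed = sprintf("%.1f ± %.1f", mean(x1, na.rm = TRUE), sd(x1, na.rm = TRUE)),
           mean_unexposed = mean(x0, na.rm = TRUE),
           mean_exposed = mean(x1, na.rm = TRUE),
           difference = mean(x1, na.rm = TRUE) - mean(x0, na.rm = TRUE),
           p_value = pv)
  })
  cat_ <- purrr::map_dfr(intersect(categorical, names(samples)), function(v) {
    x0 <- g0[[v]]; x1 <- g1[[v]]
    tab <- table(samples$exposure, samples[[v]])
    pv <- if (min(dim(tab)) < 2) 1 else suppressWarnings(chisq.test(tab)$p.value)
    p0 <- mean(x0 == max(samples[[v]], na.rm = TRUE), na.rm = TRUE)
    p1 <- mean(x1 == max(samples[[v]], na.rm = TRUE), na.rm = TRUE)
    tibble(variable = v, type = "categorical",
           unexposed = sprintf("%d (%.1f%%)", sum(x0 == max(samples[[v]], na.rm = TRUE), na.rm = TRUE), 100 * p0),
           exposed = sprintf("%d (%.1f%%)", sum(x1 == max(samples[[v]], na.rm = TRUE), na.rm = TRUE), 100 * p1),
           mean_unexposed = p0, mean_exposed = p1,
           difference = p1 - p0, p_value = pv)
  })
  dplyr::bind_rows(cont, cat_)
}
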