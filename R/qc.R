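#' Quality-control thresholds
#'
#' Detection-based filtering uses a strict `<` at the detection p-value cutoff
#' and `>=` at the fraction thresholds: a probe measurement counts as detected
#' when its detection p-value is strictly below `detection_p_cutoff`; a sample
#' is kept when at least `sample_probe_fraction` of its probes are detected,
#' and a probe is kept when it is detected in at least `probe_sample_fraction`
#' of the retained samples.
#'
#' @param detection_p_cutoff Detection p-value cutoff (default 0.05).
#' @param sample_probe_fraction Minimum fraction of detected probes a sample
#'   must have (default 0.99).
#' @param probe_sample_fraction Minimum fraction of samples in which a probe
#'   must be detected (default 0.99).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(detection_p_cutoff = 0.05,
                          sample_probe_fraction = 0.99,
                          probe_sample_fraction = 0.99) {
  check_number(detection_p_cutoff, "detection_p_cutoff",
               lower = 0, upper = 1, strict_lower = TRUE)
  check_number(sample_probe_fraction, "sample_probe_fraction",
               lower = 0, upper = 1, strict_lower = TRUE)
  check_number(probe_sample_fraction, "probe_sample_fraction",
               lower = 0, upper = 1, strict_lower = TRUE)
  structure(list(detection_p_cutoff = detection_p_cutoff,
                 sample_probe_fraction = sample_probe_fraction,
                 probe_sample_fraction = probe_sample_fraction),
            class = "qc_thresholds")
}

#' Filter samples on detection p-values
#'
#' @param detection_p Probes x samples matrix of detection p-values with
#'   sample ids as column names.
#' @param thresholds A [qc_thresholds()].
#' @return A list with character vectors `kept` and `dropped` (input order
#'   preserved).
#' @export
#' @examples
#' dp <- matrix(0.001, 10, 2, dimnames = list(NULL, c("A", "B")))
#' dp[1:5, 2] <- 0.5
#' filter_samples_by_detection(dp)
filter_samples_by_detection <- function(detection_p, thresholds = qc_thresholds()) {
  check_prob_matrix(detection_p, "detection_p")
  stopifnot(inherits(thresholds, "qc_thresholds"))
  ids <- colnames(detection_p) %||% as.character(seq_len(ncol(detection_p)))
  detected <- colMeans(detection_p < thresholds$detection_p_cutoff)
  keep <- detected >= thresholds$sample_probe_fraction
  list(kept = ids[keep], dropped = ids[!keep])
}

#' Filter probes on annotation class, chromosome and detection
#'
#' Keeps probes that are assay-class (not control), autosomal (not on X or Y)
#' and detected (p-value strictly below the cutoff) in at least
#' `probe_sample_fraction` of the samples present in `detection_p`. Intended
#' to run after sample filtering, so the detection fractions are computed over
#' retained samples; pass the unfiltered matrix to compute them over all
#' samples instead.
#'
#' @param detection_p Probes x samples detection p-value matrix (probe ids as
#'   row names), already subset to the retained samples.
#' @param annotation Probe annotation table with columns `probe_id`,
#'   `chromosome` and `probe_class`; must cover every probe.
#' @param thresholds A [qc_thresholds()].
#' @return Character vector of kept probe ids, input order preserved.
#' @export
filter_probes <- function(detection_p, annotation, thresholds = qc_thresholds()) {
  check_prob_matrix(detection_p, "detection_p")
  stopifnot(inherits(thresholds, "qc_thresholds"))
  annotation <- as_tibble(annotation)
  need <- c("probe_id", "chromosome", "probe_class")
  if (!all(need %in% names(annotation))) {
    stop_invalid("`annotation` needs columns %s", paste(need, collapse = ", "))
  }
  probes <- rownames(detection_p)
  if (is.null(probes)) stop_invalid("`detection_p` must have probe row names")
  idx <- match(probes, annotation$probe_id)
  if (anyNA(idx)) {
    stop_invalid("probes missing from annotation: %s",
                 paste(head(probes[is.na(idx)], 5), collapse = ", "))
  }
  ann <- annotation[idx, ]
  detected <- rowMeans(detection_p < thresholds$detection_p_cutoff)
  keep <- ann$probe_class != "control" &
    !(ann$chromosome %in% c("X", "Y")) &
    detected >= thresholds$probe_sample_fraction
  probes[keep]
}

stat_fun <- function(rule) {
  switch(rule,
         mean = function(x) mean(x, na.rm = TRUE),
         median = function(x) stats::median(x, na.rm = TRUE),
         mode = function(x) {
           tab <- table(x[!is.na(x)])
           v <- names(tab)[which.max(tab)]
           if (is.numeric(x)) as.numeric(v) else v
         },
         stop_invalid("unknown imputation rule '%s'", rule))
}

#' Single imputation of missing covariates
#'
#' Replaces missing entries of each named covariate by the chosen summary
#' statistic (mean, median or mode) of the non-missing values over the whole
#' sheet. When anything is imputed for a covariate, a logical provenance
#' column `<covariate>_imputed` is appended; a sheet with no missing values in
#' the ruled covariates is returned unchanged.
#'
#' @param samples Sample sheet (data frame).
#' @param rules Named character vector mapping covariate to `"mean"`,
#'   `"median"` or `"mode"`. The default uses the mean for the continuous
#'   covariates and the mode for the binary education indicator.
#' @return The sample sheet as a tibble with missing entries filled in.
#' @export
#' @examples
#' sheet <- tibble::tibble(maternal_bmi = c(20, 24, NA, 28))
#' impute_covariates(sheet, c(maternal_bmi = "mean"))
impute_covariates <- function(samples,
                              rules = c(gestational_age = "mean",
                                        maternal_age = "mean",
                                        maternal_bmi = "mean",
                                        education = "mode")) {
  samples <- as_tibble(samples)
  rules <- rules[names(rules) %in% names(samples)]
  for (cv in names(rules)) {
    x <- samples[[cv]]
    miss <- is.na(x)
    if (!any(miss)) next
    if (all(miss)) stop_invalid("covariate '%s' is entirely missing", cv)
    x[miss] <- stat_fun(rules[[cv]])(x)
    samples[[cv]] <- x
    samples[[paste0(cv, "_imputed")]] <- miss
  }
  samples
}

#' Apply the full QC stage to a cohort
#'
#' Runs the sample detection filter, then the probe filter over the retained
#' samples, subsets the cohort matrices and sample sheet accordingly, and
#' imputes missing covariates. Returns the filtered cohort together with a
#' report of every exclusion.
#'
#' @param cohort A `meth_cohort` (or any list with `beta`, `detection_p`,
#'   `samples`).
#' @param annotation Probe annotation table (see [filter_probes()]).
#' @param thresholds A [qc_thresholds()].
#' @param impute_rules Passed to [impute_covariates()]; `NULL` skips
#'   imputation.
#' @param probe_filter_first If `TRUE`, compute probe detection fractions over
#'   all samples before any sample is dropped (the alternative ordering; the
#'   default filters samples first).
#' @return A list of class `qc_result` with elements `cohort` (filtered) and
#'   `report`.
#' @export
apply_qc <- function(cohort, annotation, thresholds = qc_thresholds(),
                     impute_rules = c(gestational_age = "mean",
                                      maternal_age = "mean",
                                      maternal_bmi = "mean",
                                      education = "mode"),
                     probe_filter_first = FALSE) {
  stopifnot(is.list(cohort), !is.null(cohort$beta), !is.null(cohort$detection_p))
  samp <- filter_samples_by_detection(cohort$detection_p, thresholds)
  dp_for_probes <- if (probe_filter_first) cohort$detection_p
                   else cohort$detection_p[, samp$kept, drop = FALSE]
  probes_kept <- filter_probes(dp_for_probes, annotation, thresholds)

  ann <- as_tibble(annotation)
  ann <- ann[match(rownames(cohort$detection_p), ann$probe_id), ]
  detected <- rowMeans(
    cohort$detection_p[, samp$kept, drop = FALSE] < thresholds$detection_p_cutoff)
  dropped_control <- ann$probe_id[ann$probe_class == "control"]
  dropped_sex <- ann$probe_id[ann$chromosome %in% c("X", "Y") &
                                ann$probe_class != "control"]
  dropped_detect <- setdiff(rownames(cohort$detection_p)[
    detected < thresholds$probe_sample_fraction],
    c(dropped_control, dropped_sex))

  out <- cohort
  out$beta <- cohort$beta[probes_kept, samp$kept, drop = FALSE]
  out$detection_p <- cohort$detection_p[probes_kept, samp$kept, drop = FALSE]
  out$samples <- cohort$samples[match(samp$kept, cohort$samples$sample_id), ]
  n_imputed <- integer()
  if (!is.null(impute_rules)) {
    before <- out$samples
    out$samples <- impute_covariates(out$samples, impute_rules)
    n_imputed <- vapply(
      names(impute_rules)[names(impute_rules) %in% names(before)],
      function(cv) sum(is.na(before[[cv]])), integer(1))
  }

  report <- list(
    thresholds = unclass(thresholds),
    n_samples_in = ncol(cohort$beta),
    n_samples_kept = length(samp$kept),
    samples_dropped = samp$dropped,
    n_probes_in = nrow(cohort$beta),
    n_probes_kept = length(probes_kept),
    probes_dropped = list(control = dropped_control,
                          sex_chromosome = dropped_sex,
                          detection = dropped_detect),
    n_covariates_imputed = n_imputed,
    probe_filter_first = probe_filter_first
  )
  structure(list(cohort = out, report = report), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("<qc_result> samples %d -> %d; probes %d -> %d (control %d, sex-chr %d, detection %d)\n",
              r$n_samples_in, r$n_samples_kept, r$n_probes_in, r$n_probes_kept,
              length(r$probes_dropped$control), length(r$probes_dropped$sex_chromosome),
              length(r$probes_dropped$detection)))
  invisible(x)
}
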