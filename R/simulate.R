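#' Simulation configuration for a synthetic methylation cohort
#'
#' Bundles every generative parameter of [simulate_cohort()] into a validated
#' list. The defaults emulate a two-group cord-blood cohort of 129 newborns
#' exposed to maternal smoking and 126 unexposed, with one planted mediator
#' CpG: exposure shifts its methylation by -0.105 on the beta scale, and each
#' unit of beta adds 1190.4 g of birthweight, so the planted indirect effect
#' is about -125 g on top of a -143.3 g direct effect (total exposure effect
#' near -264 g). Cell-type composition differs between groups (different
#' Dirichlet concentrations), so cell-type adjustment is consequential
#' downstream.
#'
#' @param n_exposed,n_unexposed Group sizes.
#' @param n_probes Number of CpG probes; must be at least the number of
#'   planted effects.
#' @param true_cpg_effects Named numeric vector: probe id -> methylation shift
#'   on the beta scale (exposed minus unexposed, covariate-adjusted truth).
#' @param mediator_outcome_effects Named numeric vector: probe id -> grams of
#'   birthweight per unit beta (the generative `beta_b`). Names must be a
#'   subset of the probes present in the reference panel.
#' @param direct_exposure_effect Direct (non-mediated) exposure effect on
#'   birthweight, in grams (the generative `beta_c_prime`).
#' @param covariate_effects Named numeric vector of outcome coefficients for
#'   `sex` (1 = male), `gestational_age` (weeks), `maternal_age` (years),
#'   `maternal_bmi` (kg/m^2) and `education` (1 = university).
#' @param cell_type_count Number of leukocyte types (default 6).
#' @param dirichlet_concentrations List with elements `unexposed` and
#'   `exposed`, each a positive vector of length `cell_type_count`. Unequal
#'   vectors create cell-composition confounding.
#' @param noise_sd_beta SD of additive Gaussian probe noise on the beta scale
#'   (clipped to \[0, 1\] afterwards).
#' @param mediator_sd_beta Extra between-individual biological variability (SD
#'   on the beta scale) at the mediator CpGs, on top of `noise_sd_beta`. Real
#'   smoking-responsive CpGs vary substantially between individuals within a
#'   group; this variability is what transmits to the outcome and makes the
#'   mediator-to-outcome coefficient estimable with a realistic standard
#'   error (default 0.09, which puts `se_b` near the order reported for the
#'   discovery cohort at n = 255).
#' @param noise_sd_outcome SD of the birthweight residual, grams.
#' @param missing_covariate_rate Per-entry missingness probability applied to
#'   gestational age, maternal BMI and education (the covariates the QC stage
#'   imputes).
#' @param detection_fail_rate Per-entry probability that a detection p-value
#'   is drawn from the failing range instead of near zero.
#' @param n_failed_samples Number of whole samples planted with an elevated
#'   probe-failure rate, to exercise the sample-level QC filter.
#' @param seed Integer seed; identical seed and config give a bit-identical
#'   dataset.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_probes = 200, seed = 7)
#' cfg$n_exposed
sim_config <- function(n_exposed = 129,
                       n_unexposed = 126,
                       n_probes = 1000,
                       true_cpg_effects = c(cg09935388 = -0.105),
                       mediator_outcome_effects = c(cg09935388 = 1190.4),
                       direct_exposure_effect = -143.3,
                       covariate_effects = c(sex = 120, gestational_age = 150,
                                             maternal_age = 0, maternal_bmi = 15,
                                             education = 30),
                       cell_type_count = 6,
                       dirichlet_concentrations = NULL,
                       noise_sd_beta = 0.02,
                       mediator_sd_beta = 0.09,
                       noise_sd_outcome = 450,
                       missing_covariate_rate = 0.02,
                       detection_fail_rate = 0.002,
                       n_failed_samples = 0,
                       seed = 1L) {
  n_exposed <- check_count(n_exposed, "n_exposed")
  n_unexposed <- check_count(n_unexposed, "n_unexposed")
  n_probes <- check_count(n_probes, "n_probes")
  cell_type_count <- check_count(cell_type_count, "cell_type_count")
  check_number(noise_sd_beta, "noise_sd_beta", lower = 0)
  check_number(mediator_sd_beta, "mediator_sd_beta", lower = 0)
  check_number(noise_sd_outcome, "noise_sd_outcome", lower = 0)
  check_number(missing_covariate_rate, "missing_covariate_rate",
               lower = 0, upper = 1, strict_upper = TRUE)
  check_number(detection_fail_rate, "detection_fail_rate", lower = 0, upper = 1)
  n_failed_samples <- check_count(n_failed_samples, "n_failed_samples", min = 0L)

  if (length(true_cpg_effects) > 0 && is.null(names(true_cpg_effects))) {
    stop_invalid("`true_cpg_effects` must be named by probe id")
  }
  if (length(mediator_outcome_effects) > 0 && is.null(names(mediator_outcome_effects))) {
    stop_invalid("`mediator_outcome_effects` must be named by probe id")
  }
  if (n_probes < length(true_cpg_effects)) {
    stop_invalid("`n_probes` (%d) is smaller than the number of planted effects (%d)",
                 n_probes, length(true_cpg_effects))
  }

  if (is.null(dirichlet_concentrations)) {
    # Cord-blood-like mix, granulocyte dominated; exposed group skewed towards
    # granulocytes so composition confounds the exposure.
    base <- c(8, 50, 8, 6, 20, 8)
    shift <- c(6, 58, 8, 5, 15, 6)
    if (cell_type_count != 6) {
      base <- rep(10, cell_type_count)
      shift <- rep(10, cell_type_count)
      shift[1] <- 14
    }
    dirichlet_concentrations <- list(unexposed = base, exposed = shift)
  }
  for (grp in c("unexposed", "exposed")) {
    conc <- dirichlet_concentrations[[grp]]
    if (is.null(conc) || length(conc) != cell_type_count || any(conc <= 0)) {
      stop_invalid("`dirichlet_concentrations$%s` must be %d positive values",
                   grp, cell_type_count)
    }
  }

  structure(
    list(
      n_exposed = n_exposed, n_unexposed = n_unexposed, n_probes = n_probes,
      true_cpg_effects = true_cpg_effects,
      mediator_outcome_effects = mediator_outcome_effects,
      direct_exposure_effect = direct_exposure_effect,
      covariate_effects = covariate_effects,
      cell_type_count = cell_type_count,
      dirichlet_concentrations = dirichlet_concentrations,
      noise_sd_beta = noise_sd_beta,
      mediator_sd_beta = mediator_sd_beta,
      noise_sd_outcome = noise_sd_outcome,
      missing_covariate_rate = missing_covariate_rate,
      detection_fail_rate = detection_fail_rate,
      n_failed_samples = n_failed_samples,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

default_cell_types <- function(n = 6) {
  if (n == 6) c("Bcell", "Gran", "Mono", "NK", "CD4T", "CD8T")
  else paste0("CT", seq_len(n))
}

#' Generate a synthetic cell-type reference signature panel
#'
#' Builds a probes-by-cell-types matrix of mean beta values, playing the role
#' a sorted-leukocyte reference panel plays in reference-based deconvolution.
#' The first `n_discriminating` probes are markers: each is high (by at least
#' `separation` on the beta scale) in exactly one cell type, which guarantees
#' full column rank and makes deconvolution identifiable. Remaining probes are
#' near-constant across types.
#'
#' @param n_probes Number of probes (rows); must be at least `n_types`.
#' @param n_types Number of cell types (columns, default 6).
#' @param separation Minimum beta-scale spread between the marker type and the
#'   other types at a discriminating probe; in (0, 0.9].
#' @param seed Integer seed.
#' @param n_discriminating Number of marker probes; defaults to
#'   `min(n_probes, 10 * n_types)` and is never below `n_types`.
#' @param probe_ids Optional character vector of probe ids (length
#'   `n_probes`); defaults to `cg00000001`-style ids.
#' @param planted_probes Probe ids to substitute at the tail of the default id
#'   vector (always non-discriminating rows), so that downstream planted
#'   effects can refer to recognisable names.
#'
#' @return A list of class `meth_reference` with elements `signature`
#'   (matrix), `cell_types` and `discriminating_probes`.
#' @export
#' @examples
#' ref <- simulate_reference(100, seed = 1)
#' dim(ref$signature)
simulate_reference <- function(n_probes, n_types = 6, separation = 0.3,
                               seed = 1L, n_discriminating = NULL,
                               probe_ids = NULL, planted_probes = character()) {
  n_probes <- check_count(n_probes, "n_probes")
  n_types <- check_count(n_types, "n_types")
  check_number(separation, "separation", lower = 0, upper = 0.9,
               strict_lower = TRUE)
  if (n_probes < n_types) {
    stop_invalid("`n_probes` (%d) must be at least `n_types` (%d)",
                 n_probes, n_types)
  }
  n_disc <- n_discriminating %||%
    max(n_types, min(n_probes - length(planted_probes), 10L * n_types))
  n_disc <- check_count(n_disc, "n_discriminating", min = n_types)
  if (n_disc > n_probes) stop_invalid("`n_discriminating` exceeds `n_probes`")

  if (is.null(probe_ids)) {
    probe_ids <- sprintf("cg%08d", seq_len(n_probes))
    if (length(planted_probes) > 0) {
      if (n_disc + length(planted_probes) > n_probes) {
        stop_invalid("not enough non-discriminating probes to host %d planted ids",
                     length(planted_probes))
      }
      probe_ids[(n_probes - length(planted_probes) + 1L):n_probes] <- planted_probes
    }
  } else if (length(probe_ids) != n_probes || anyDuplicated(probe_ids) > 0) {
    stop_invalid("`probe_ids` must be %d unique ids", n_probes)
  }

  types <- default_cell_types(n_types)
  sig <- withr::with_seed(as.integer(seed), {
    m <- matrix(NA_real_, n_probes, n_types)
    marker <- rep_len(seq_len(n_types), n_disc)
    low <- runif(n_disc, 0.05, max(0.05, 0.95 - separation))
    for (i in seq_len(n_disc)) {
      row <- pmax(low[i] - runif(n_types, 0, 0.02), 0.01)
      row[marker[i]] <- low[i] + separation
      m[i, ] <- row
    }
    if (n_disc < n_probes) {
      idx <- (n_disc + 1L):n_probes
      base <- runif(length(idx), 0.1, 0.9)
      m[idx, ] <- pmin(pmax(base + rnorm(length(idx) * n_types, 0, 0.01), 0), 1)
    }
    m
  })
  dimnames(sig) <- list(probe_ids, types)

  structure(
    list(signature = sig, cell_types = types,
         discriminating_probes = probe_ids[seq_len(n_disc)]),
    class = "meth_reference"
  )
}

#' Generate a synthetic probe annotation table
#'
#' Assigns each probe a chromosome, a (placeholder) gene symbol, a probe class
#' and a CpG-island relation, planting configurable fractions of control
#' probes and sex-chromosome probes for the QC filters to remove. Probes named
#' in `always_keep` (e.g. planted mediator CpGs) are forced to be autosomal
#' assay probes.
#'
#' @param probe_ids Character vector of probe ids.
#' @param frac_control Fraction of control-class probes.
#' @param frac_sex_chr Fraction of probes placed on X or Y.
#' @param always_keep Probe ids guaranteed autosomal and assay-class.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `probe_id`, `chromosome`, `gene`,
#'   `probe_class`, `island_relation`.
#' @export
simulate_annotation <- function(probe_ids, frac_control = 0.01,
                                frac_sex_chr = 0.03, always_keep = character(),
                                seed = 1L) {
  if (length(probe_ids) == 0 || anyDuplicated(probe_ids) > 0) {
    stop_invalid("`probe_ids` must be a non-empty vector of unique ids")
  }
  n <- length(probe_ids)
  withr::with_seed(as.integer(seed), {
    chromosome <- sample(as.character(1:22), n, replace = TRUE)
    n_sex <- round(frac_sex_chr * n)
    n_ctrl <- round(frac_control * n)
    eligible <- setdiff(seq_len(n), match(always_keep, probe_ids))
    sex_idx <- sample(eligible, min(n_sex, length(eligible)))
    chromosome[sex_idx] <- sample(c("X", "Y"), length(sex_idx),
                                  replace = TRUE, prob = c(0.9, 0.1))
    probe_class <- rep("assay", n)
    ctrl_pool <- setdiff(eligible, sex_idx)
    ctrl_idx <- sample(ctrl_pool, min(n_ctrl, length(ctrl_pool)))
    probe_class[ctrl_idx] <- "control"
    tibble(
      probe_id = probe_ids,
      chromosome = chromosome,
      gene = paste0("GENE", sample.int(max(2L, n %/% 5L), n, replace = TRUE)),
      probe_class = probe_class,
      island_relation = sample(c("island", "shore", "shelf", "open_sea"),
                               n, replace = TRUE,
                               prob = c(0.3, 0.25, 0.1, 0.35))
    )
  })
}

rdirichlet_mat <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

#' Generate one synthetic methylation cohort
#'
#' Draws per-sample cell proportions from group-specific Dirichlet
#' distributions, forms baseline methylation as the reference signature mixed
#' by those proportions, plants the configured exposure shifts at the true
#' CpGs, adds clipped Gaussian probe noise, and generates birthweight as
#' direct exposure effect + mediator contributions (grams per unit of the
#' *realised* beta) + covariate effects + Gaussian noise. Detection p-values
#' sit near zero with planted failures. The full generative truth (including
#' true cell proportions) is kept in the `truth` element.
#'
#' @param config A [sim_config()].
#' @param reference A [simulate_reference()] panel with `config$n_probes` rows
#'   containing every planted probe id.
#' @param clip_tolerance Maximum amount an *expected* (pre-noise) beta may
#'   exceed \[0, 1\] before the planted effects are rejected as invalid.
#'
#' @return A list of class `meth_cohort`: `beta` and `detection_p` (probes x
#'   samples matrices), `samples` (tibble sample sheet) and `truth`.
#' @export
#' @examples
#' ref <- simulate_reference(50, seed = 1, planted_probes = "cg09935388")
#' cohort <- simulate_cohort(sim_config(n_probes = 50, seed = 2), ref)
#' dim(cohort$beta)
simulate_cohort <- function(config, reference, clip_tolerance = 0.02) {
  stopifnot(inherits(config, "sim_config"), inherits(reference, "meth_reference"))
  sig <- reference$signature
  if (nrow(sig) != config$n_probes) {
    stop_invalid("reference has %d probes but config expects %d",
                 nrow(sig), config$n_probes)
  }
  planted <- names(config$true_cpg_effects)
  missing_planted <- setdiff(planted, rownames(sig))
  if (length(missing_planted) > 0) {
    stop_invalid("planted probes not in reference: %s",
                 paste(missing_planted, collapse = ", "))
  }
  med_probes <- names(config$mediator_outcome_effects)
  if (length(setdiff(med_probes, rownames(sig))) > 0) {
    stop_invalid("mediator probes not in reference: %s",
                 paste(setdiff(med_probes, rownames(sig)), collapse = ", "))
  }
  if (ncol(sig) != config$cell_type_count) {
    stop_invalid("reference has %d cell types but config expects %d",
                 ncol(sig), config$cell_type_count)
  }

  n_unexp <- config$n_unexposed
  n_exp <- config$n_exposed
  n <- n_unexp + n_exp
  exposure <- rep(c(0L, 1L), c(n_unexp, n_exp))
  sample_ids <- sprintf("S%04d", seq_len(n))

  withr::with_seed(config$seed, {
    # --- cell proportions, group-specific Dirichlet ---
    props <- matrix(NA_real_, n, config$cell_type_count,
                    dimnames = list(sample_ids, reference$cell_types))
    props[exposure == 0L, ] <-
      rdirichlet_mat(n_unexp, config$dirichlet_concentrations$unexposed)
    props[exposure == 1L, ] <-
      rdirichlet_mat(n_exp, config$dirichlet_concentrations$exposed)

    # --- methylation: mixture baseline + planted shifts + clipped noise ---
    expected <- sig %*% t(props)               # probes x samples
    if (length(planted) > 0) {
      expected[planted, exposure == 1L] <-
        expected[planted, exposure == 1L] + config$true_cpg_effects
    }
    if (length(planted) > 0) {
      rng <- range(expected[planted, , drop = FALSE])
      if (rng[1] < -clip_tolerance || rng[2] > 1 + clip_tolerance) {
        stop_invalid(
          "planted effects push expected beta to [%.3f, %.3f], outside [0,1] beyond the clipping tolerance %.3f",
          rng[1], rng[2], clip_tolerance)
      }
    }
    if (length(med_probes) > 0 && config$mediator_sd_beta > 0) {
      # between-individual biological variability at the mediator CpGs; this
      # is the variation that transmits to the outcome
      expected[med_probes, ] <- expected[med_probes, , drop = FALSE] +
        rnorm(length(med_probes) * n, 0, config$mediator_sd_beta)
    }
    noisy <- expected + rnorm(length(expected), 0, config$noise_sd_beta)
    clipped_fraction <- mean(noisy < 0 | noisy > 1)
    beta <- pmin(pmax(noisy, 0), 1)

    # --- covariates, loosely matched to the two-group cohort profile ---
    sex <- rbinom(n, 1, 0.53)
    gestational_age <- round(39.8 - 0.1 * exposure +
                               rnorm(n, 0, 1.2 + 0.1 * exposure), 1)
    gestational_age <- pmax(gestational_age, 37.1)  # premature excluded upstream
    maternal_age <- round(31.1 - 1.4 * exposure +
                            rnorm(n, 0, 3.6 + 1.1 * exposure), 1)
    education <- rbinom(n, 1, ifelse(exposure == 1L, 0.186, 0.444))
    maternal_bmi <- round(23.9 + 1.0 * exposure +
                            rnorm(n, 0, 3.3 + 1.8 * exposure), 1)
    maternal_bmi <- pmax(maternal_bmi, 16)
    plate <- sample(rep_len(paste0("P", 1:3), n))
    cigarettes_per_day <- ifelse(
      exposure == 1L,
      pmin(pmax(round(rlnorm(n, log(10), 0.55)), 1), 30),
      NA_real_)
    paternal_smoking <- ifelse(exposure == 1L, rbinom(n, 1, 0.30), 0L)

    # --- outcome: direct effect + mediators (realised beta) + covariates ---
    cov_mat <- cbind(sex = sex, gestational_age = gestational_age,
                     maternal_age = maternal_age, maternal_bmi = maternal_bmi,
                     education = education)
    cov_eff <- config$covariate_effects[colnames(cov_mat)]
    cov_eff[is.na(cov_eff)] <- 0
    lp <- config$direct_exposure_effect * exposure +
      drop(cov_mat %*% cov_eff)
    if (length(med_probes) > 0) {
      lp <- lp + drop(crossprod(beta[med_probes, , drop = FALSE],
                                config$mediator_outcome_effects))
    }
    intercept <- 3685 - mean(lp[exposure == 0L])
    birthweight <- round(intercept + lp + rnorm(n, 0, config$noise_sd_outcome))

    # --- detection p-values: near zero, with planted failures ---
    detection_p <- matrix(runif(length(beta), 0, 0.02),
                          nrow = nrow(beta), dimnames = dimnames(beta))
    fail <- matrix(runif(length(beta)) < config$detection_fail_rate,
                   nrow = nrow(beta))
    detection_p[fail] <- runif(sum(fail), 0.05, 1)
    failed_samples <- character()
    if (config$n_failed_samples > 0) {
      failed_idx <- sample.int(n, config$n_failed_samples)
      failed_samples <- sample_ids[failed_idx]
      for (j in failed_idx) {
        bad <- runif(nrow(beta)) < 0.05
        detection_p[bad, j] <- runif(sum(bad), 0.05, 1)
      }
    }

    samples <- tibble(
      sample_id = sample_ids,
      exposure = exposure,
      birthweight = birthweight,
      sex = sex,
      gestational_age = gestational_age,
      maternal_age = maternal_age,
      maternal_bmi = maternal_bmi,
      education = education,
      plate = plate,
      cigarettes_per_day = cigarettes_per_day,
      paternal_smoking = paternal_smoking
    )
    # plant covariate missingness on the covariates the QC stage imputes
    if (config$missing_covariate_rate > 0) {
      for (cv in c("gestational_age", "maternal_bmi", "education")) {
        miss <- runif(n) < config$missing_covariate_rate
        samples[[cv]][miss] <- NA
      }
    }

    dimnames(beta) <- list(rownames(sig), sample_ids)
    dimnames(detection_p) <- dimnames(beta)

    structure(
      list(
        beta = beta,
        detection_p = detection_p,
        samples = samples,
        truth = list(
          config = config,
          cell_proportions = as_tibble(cbind(tibble(sample_id = sample_ids),
                                             as.data.frame(props))),
          planted_shifts = config$true_cpg_effects,
          mediator_outcome_effects = config$mediator_outcome_effects,
          direct_exposure_effect = config$direct_exposure_effect,
          intercept = intercept,
          clipped_fraction = clipped_fraction,
          failed_samples = failed_samples
        )
      ),
      class = "meth_cohort"
    )
  })
}

#' Generate multiple cohorts sharing true effects at common probes
#'
#' Produces one cohort per configuration against a single shared reference
#' panel, so all cohorts share a probe set. When `shared_truth` is supplied it
#' overrides the planted methylation shift and the mediator-to-outcome effect
#' in every configuration at those probes, giving the common true effects a
#' fixed-effects meta-analysis assumes; cohorts still differ in size, noise
#' and covariate structure, and each uses its own seed.
#'
#' @param configs List of at least two [sim_config()] objects.
#' @param reference Shared [simulate_reference()] panel.
#' @param shared_truth Optional tibble/data.frame with columns `probe_id`,
#'   `shift`, `outcome_effect`.
#'
#' @return A list of `meth_cohort` objects (named `cohort1`, `cohort2`, ...).
#' @export
simulate_cohorts <- function(configs, reference, shared_truth = NULL) {
  if (!is.list(configs) || length(configs) < 2) {
    stop_invalid("`configs` must be a list of at least two sim_config objects")
  }
  for (cfg in configs) {
    if (!inherits(cfg, "sim_config")) {
      stop_invalid("every element of `configs` must be a sim_config")
    }
    if (cfg$n_probes != nrow(reference$signature)) {
      stop_invalid("config probe count %d does not match the shared reference (%d probes)",
                   cfg$n_probes, nrow(reference$signature))
    }
  }
  if (!is.null(shared_truth)) {
    shared_truth <- as_tibble(shared_truth)
    need <- c("probe_id", "shift", "outcome_effect")
    if (!all(need %in% names(shared_truth))) {
      stop_invalid("`shared_truth` needs columns %s", paste(need, collapse = ", "))
    }
    bad <- setdiff(shared_truth$probe_id, rownames(reference$signature))
    if (length(bad) > 0) {
      stop_invalid("shared probes not in reference: %s", paste(bad, collapse = ", "))
    }
    configs <- lapply(configs, function(cfg) {
      shifts <- cfg$true_cpg_effects
      shifts[shared_truth$probe_id] <- shared_truth$shift
      eff <- cfg$mediator_outcome_effects
      eff[shared_truth$probe_id] <- shared_truth$outcome_effect
      cfg$true_cpg_effects <- shifts
      cfg$mediator_outcome_effects <- eff
      cfg
    })
  }
  out <- lapply(configs, simulate_cohort, reference = reference)
  names(out) <- paste0("cohort", seq_along(out))
  out
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf("<meth_cohort> %d probes x %d samples (%d exposed / %d unexposed)\n",
              nrow(x$beta), ncol(x$beta),
              sum(x$samples$exposure == 1), sum(x$samples$exposure == 0)))
  invisible(x)
}

#' @export
print.meth_reference <- function(x, ...) {
  cat(sprintf("<meth_reference> %d probes x %d cell types (%d discriminating)\n",
              nrow(x$signature), length(x$cell_types),
              length(x$discriminating_probes)))
  invisible(x)
}
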