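# End-to-end orchestration: simulate -> qc -> celltype -> ewas -> mediate
# (-> meta across cohorts), with flat-file intermediates and a manifest that
# is sufficient to re-run bit-identically.

#' Pipeline configuration
#'
#' @param out_dir Output directory for every intermediate table and the
#'   manifest.
#' @param seed Master seed; all stage seeds are split from it.
#' @param n_cohorts Number of cohorts to simulate (1 = discovery only; more
#'   adds replication cohorts and a meta stage).
#' @param sim Either a single [sim_config()]/list of them (one per cohort) or
#'   `NULL` to use defaults sized like the study cohorts (255, then 678 and
#'   745 for replication cohorts).
#' @param thresholds A [qc_thresholds()].
#' @param covariates EWAS covariate list.
#' @param adjust_cell_types Include estimated cell proportions as covariates.
#' @param sensitivity_no_cells Additionally run the EWAS without cell-type
#'   adjustment and write it under its own name.
#' @param mediation_probes Probes to mediate; `NULL` means planted truth
#'   probes plus any FDR < 0.05 hits.
#' @param fdr_cutoff FDR threshold used to pick mediation probes.
#' @param yaml_path Optionally read all of the above from a YAML file
#'   (top-level keys matching these argument names; `sim` entries are passed
#'   to [sim_config()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("methmediate_run_"),
                            seed = 1L,
                            n_cohorts = 1L,
                            sim = NULL,
                            thresholds = qc_thresholds(),
                            covariates = ewas_covariates(),
                            adjust_cell_types = TRUE,
                            sensitivity_no_cells = FALSE,
                            mediation_probes = NULL,
                            fdr_cutoff = 0.05,
                            yaml_path = NULL) {
  if (!is.null(yaml_path)) {
    y <- yaml::read_yaml(yaml_path)
    if (!is.null(y$sim)) y$sim <- lapply(y$sim, function(s) do.call(sim_config, s))
    if (!is.null(y$thresholds)) y$thresholds <- do.call(qc_thresholds, y$thresholds)
    args <- modifyList(
      list(out_dir = out_dir, seed = seed, n_cohorts = n_cohorts, sim = sim,
           thresholds = thresholds, covariates = covariates,
           adjust_cell_types = adjust_cell_types,
           sensitivity_no_cells = sensitivity_no_cells,
           mediation_probes = mediation_probes, fdr_cutoff = fdr_cutoff),
      y)
    return(do.call(pipeline_config, args))
  }
  n_cohorts <- check_count(n_cohorts, "n_cohorts")
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), n_cohorts = n_cohorts,
         sim = sim, thresholds = thresholds, covariates = covariates,
         adjust_cell_types = isTRUE(adjust_cell_types),
         sensitivity_no_cells = isTRUE(sensitivity_no_cells),
         mediation_probes = mediation_probes, fdr_cutoff = fdr_cutoff),
    class = "pipeline_config")
}

default_cohort_sizes <- list(c(129L, 126L), c(65L, 613L), c(110L, 635L))

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)),
                 class = "methmediate_stage_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate, QC, cell-type deconvolution, EWAS, mediation and (for
#' multi-cohort runs) fixed-effects meta-analysis, writing every intermediate
#' table under `config$out_dir` and a `manifest.json` recording seeds,
#' thresholds, per-stage row/column counts and MD5 hashes of every written
#' file. Re-running the same config reproduces every file bit-identically.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (a list of class `pipeline_manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- split_seed(config$seed, 3L + config$n_cohorts)

  # --- configs and shared simulation inputs ---
  sims <- config$sim
  if (!is.null(sims) && inherits(sims, "sim_config")) sims <- list(sims)
  if (is.null(sims)) {
    sims <- lapply(seq_len(config$n_cohorts), function(i) {
      sz <- default_cohort_sizes[[min(i, length(default_cohort_sizes))]]
      sim_config(n_exposed = sz[1], n_unexposed = sz[2],
                 seed = seeds[3L + i])
    })
  }
  if (length(sims) != config$n_cohorts) {
    stop_invalid("`sim` supplies %d configs for %d cohorts",
                 length(sims), config$n_cohorts)
  }
  n_probes <- sims[[1]]$n_probes
  planted <- unique(unlist(lapply(sims, function(s) names(s$true_cpg_effects))))

  manifest <- list(package_version = as.character(utils::packageVersion("methmediate")),
                   seed = config$seed,
                   thresholds = unclass(config$thresholds),
                   covariates = config$covariates,
                   stages = list(), files = list())
  record_file <- function(path) {
    manifest$files[[basename(path)]] <<- digest::digest(file = path, algo = "md5")
  }

  ref <- stage("simulate", {
    simulate_reference(n_probes, seed = seeds[1], planted_probes = planted)
  })
  annotation <- stage("simulate", {
    simulate_annotation(rownames(ref$signature), always_keep = planted,
                        seed = seeds[2])
  })
  cohorts <- stage("simulate", {
    if (config$n_cohorts == 1) list(cohort1 = simulate_cohort(sims[[1]], ref))
    else simulate_cohorts(sims, ref)
  })
  write_annotation(annotation, file.path(config$out_dir, "annotation.tsv"))
  record_file(file.path(config$out_dir, "annotation.tsv"))

  ewas_list <- list(); med_list <- list()
  for (i in seq_along(cohorts)) {
    label <- names(cohorts)[i]
    cdir <- file.path(config$out_dir, label)
    write_cohort(cohorts[[i]], cdir)
    for (f in c("beta.tsv", "detection_p.tsv", "samples.csv")) {
      record_file(file.path(cdir, f))
    }

    qc <- stage("qc", apply_qc(cohorts[[i]], annotation, config$thresholds))
    jsonlite::write_json(qc$report, file.path(cdir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    record_file(file.path(cdir, "qc_report.json"))

    props <- stage("celltype", {
      if (config$adjust_cell_types) estimate_cell_proportions(qc$cohort, ref)
      else NULL
    })
    if (!is.null(props)) {
      write_results(props, file.path(cdir, "cell_proportions.csv"))
      record_file(file.path(cdir, "cell_proportions.csv"))
    }

    ew <- stage("ewas", run_ewas(qc$cohort, props, config$covariates))
    write_results(ew, file.path(cdir, "ewas.tsv"))
    record_file(file.path(cdir, "ewas.tsv"))
    if (config$sensitivity_no_cells && config$adjust_cell_types) {
      ew0 <- stage("ewas", run_ewas(qc$cohort, NULL, config$covariates))
      write_results(ew0, file.path(cdir, "ewas_no_cell_correction.tsv"))
      record_file(file.path(cdir, "ewas_no_cell_correction.tsv"))
    }

    med_probes <- config$mediation_probes %||%
      union(intersect(planted, ew$probe_id),
            ew$probe_id[ew$q < config$fdr_cutoff])
    med <- stage("mediation", {
      run_mediation(qc$cohort, props, med_probes, config$covariates)
    })
    write_results(med, file.path(cdir, "mediation.tsv"))
    record_file(file.path(cdir, "mediation.tsv"))

    ewas_list[[label]] <- ew
    med_list[[label]] <- med
    manifest$stages[[label]] <- list(
      n_samples_simulated = ncol(cohorts[[i]]$beta),
      n_samples_kept = qc$report$n_samples_kept,
      n_probes_simulated = nrow(cohorts[[i]]$beta),
      n_probes_kept = qc$report$n_probes_kept,
      n_probes_tested = nrow(ew),
      n_mediation_probes = nrow(med),
      sim_seed = sims[[i]]$seed)
  }

  if (config$n_cohorts > 1) {
    meta_out <- stage("meta", {
      probes <- Reduce(intersect, lapply(med_list, function(m) m$probe_id))
      purrr::map_dfr(probes, function(pb) {
        ew_rows <- purrr::imap_dfr(ewas_list, function(e, lab) {
          r <- e[e$probe_id == pb, ]
          tibble(cohort = lab, effect = r$coefficient, se = r$se)
        })
        med_rows <- purrr::imap_dfr(med_list, function(m, lab) {
          r <- m[m$probe_id == pb, ]
          tibble(cohort = lab, effect = r$delta, se = r$se_delta, p = r$sobel_p,
                 stage = if (lab == "cohort1") "discovery" else "replication")
        })
        em <- fixed_effects_meta(ew_rows)
        mm <- meta_mediation(med_rows)
        dplyr::bind_cols(tibble(probe_id = pb,
                                pooled_methylation_difference = em$pooled_effect,
                                pooled_methylation_p = em$p), mm)
      })
    })
    write_results(meta_out, file.path(config$out_dir, "meta.tsv"))
    record_file(file.path(config$out_dir, "meta.tsv"))
    manifest$stages$meta <- list(n_probes_pooled = nrow(meta_out))
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  class(manifest) <- "pipeline_manifest"
  invisible(manifest)
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("<pipeline_manifest> seed %d, %d stage record(s), %d file(s)\n",
              x$seed, length(x$stages), length(x$files)))
  invisible(x)
}
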