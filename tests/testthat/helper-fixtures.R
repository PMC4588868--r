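# Shared synthetic fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, fn(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Discovery-sized cohort (255 samples, 300 probes) with one planted mediator
# CpG, passed through QC and deconvolution.
study_fixture <- function() {
  fixture("study", function() {
    ref <- simulate_reference(300, seed = 11, planted_probes = "cg09935388")
    cfg <- sim_config(n_probes = 300, seed = 12)
    cohort <- simulate_cohort(cfg, ref)
    ann <- simulate_annotation(rownames(ref$signature),
                               always_keep = "cg09935388", seed = 13)
    qc <- apply_qc(cohort, ann)
    props <- estimate_cell_proportions(qc$cohort, ref)
    list(ref = ref, cfg = cfg, raw = cohort, ann = ann,
         cohort = qc$cohort, report = qc$report, props = props)
  })
}

# Null cohort: no planted effects anywhere, 255 samples.
null_fixture <- function(n_probes = 400, seed = 21) {
  fixture(paste0("null", n_probes), function() {
    ref <- simulate_reference(n_probes, seed = seed)
    cfg <- sim_config(n_probes = n_probes, true_cpg_effects = numeric(),
                      mediator_outcome_effects = numeric(),
                      direct_exposure_effect = 0,
                      missing_covariate_rate = 0, seed = seed + 1)
    cohort <- simulate_cohort(cfg, ref)
    props <- estimate_cell_proportions(cohort, ref)
    list(ref = ref, cohort = cohort, props = props)
  })
}
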