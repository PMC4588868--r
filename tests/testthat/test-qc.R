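test_that("sample detection filter matches a brute-force count and honours the strict cutoff", {
  dp <- matrix(0.001, nrow = 100, ncol = 3,
               dimnames = list(sprintf("p%03d", 1:100), c("A", "B", "C")))
  dp[1:2, "B"] <- 0.5      # 98% of B's probes detected: below the 99% bar
  res <- filter_samples_by_detection(dp)
  expect_identical(res$kept, c("A", "C"))
  expect_identical(res$dropped, "B")

  # brute-force recount of the rule
  frac <- sapply(colnames(dp), function(s) sum(dp[, s] < 0.05) / nrow(dp))
  expect_identical(res$kept, names(frac)[frac >= 0.99])

  # a probe sitting exactly at the cutoff counts as failing (strict <)
  dp2 <- matrix(0.05, nrow = 10, ncol = 1, dimnames = list(NULL, "S"))
  expect_identical(filter_samples_by_detection(dp2)$dropped, "S")
  dp2[] <- 0.049999
  expect_identical(filter_samples_by_detection(dp2)$kept, "S")

  expect_error(filter_samples_by_detection(matrix(numeric(), 0, 0)),
               class = "methmediate_invalid_argument")
})

test_that("probe filter removes control, sex-chromosome and undetected probes", {
  n_samp <- 100
  probes <- sprintf("p%02d", 1:10)
  dp <- matrix(0.001, nrow = 10, ncol = n_samp,
               dimnames = list(probes, sprintf("S%03d", 1:n_samp)))
  dp["p03", 1:5] <- 0.9    # detected in only 95% of samples
  ann <- tibble::tibble(
    probe_id = probes,
    chromosome = c("1", "2", "3", "4", "X", "6", "7", "8", "9", "10"),
    gene = "",
    probe_class = c("assay", "control", rep("assay", 8)))
  kept <- filter_probes(dp, ann)
  expect_identical(kept, setdiff(probes, c("p02", "p03", "p05")))

  expect_error(filter_probes(dp, ann[-1, ]),
               class = "methmediate_invalid_argument")
  expect_match(tryCatch(filter_probes(dp, ann[-1, ]), error = conditionMessage),
               "p01")

  # all autosomal assay probes at p = 0 are kept
  dp0 <- matrix(0, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  ann0 <- tibble::tibble(probe_id = c("a", "b", "c"), chromosome = "1",
                         gene = "", probe_class = "assay")
  expect_identical(filter_probes(dp0, ann0), c("a", "b", "c"))
})

test_that("each QC filter is idempotent on its own output", {
  fx <- study_fixture()
  dp <- fx$raw$detection_p
  s1 <- filter_samples_by_detection(dp)
  s2 <- filter_samples_by_detection(dp[, s1$kept, drop = FALSE])
  expect_identical(s2$kept, s1$kept)
  expect_length(s2$dropped, 0)

  p1 <- filter_probes(dp[, s1$kept, drop = FALSE], fx$ann)
  p2 <- filter_probes(dp[p1, s1$kept, drop = FALSE], fx$ann)
  expect_identical(p2, p1)
})

test_that("whole-sample detection failures are caught by the sample filter", {
  ref <- simulate_reference(400, seed = 41)
  cfg <- sim_config(n_probes = 400, n_exposed = 20, n_unexposed = 20,
                    true_cpg_effects = numeric(),
                    mediator_outcome_effects = numeric(),
                    n_failed_samples = 2, seed = 42)
  co <- simulate_cohort(cfg, ref)
  res <- filter_samples_by_detection(co$detection_p)
  expect_setequal(res$dropped, co$truth$failed_samples)
})

test_that("imputation fills missing entries with the requested statistic and flags them", {
  sheet <- tibble::tibble(
    sample_id = paste0("S", 1:4),
    maternal_bmi = c(20, 24, NA, 28),
    gestational_age = c(38, 40, 40, NA),
    education = c(0, 1, NA, 0))
  out <- impute_covariates(sheet, c(maternal_bmi = "mean",
                                    gestational_age = "median",
                                    education = "mode"))
  expect_equal(out$maternal_bmi[3], 24)
  expect_equal(out$gestational_age[4], 40)
  expect_equal(out$education[3], 0)
  expect_identical(out$maternal_bmi_imputed, c(FALSE, FALSE, TRUE, FALSE))

  # non-missing entries are untouched
  expect_identical(out$maternal_bmi[-3], sheet$maternal_bmi[-3])

  # nothing missing: the sheet comes back bit-identical
  full <- tibble::tibble(sample_id = "S1", maternal_bmi = 22)
  expect_identical(impute_covariates(full, c(maternal_bmi = "mean")), full)

  # entirely missing covariate is an error
  allna <- tibble::tibble(maternal_bmi = c(NA_real_, NA_real_))
  expect_error(impute_covariates(allna, c(maternal_bmi = "mean")),
               class = "methmediate_invalid_argument")
})

test_that("the alternative probe-filter ordering is exposed and differs only via dropped samples", {
  ref <- simulate_reference(300, seed = 51)
  cfg <- sim_config(n_probes = 300, n_exposed = 30, n_unexposed = 30,
                    true_cpg_effects = numeric(),
                    mediator_outcome_effects = numeric(),
                    n_failed_samples = 1, detection_fail_rate = 0.005,
                    seed = 52)
  co <- simulate_cohort(cfg, ref)
  ann <- simulate_annotation(rownames(co$beta), seed = 53)
  after <- apply_qc(co, ann, probe_filter_first = FALSE)
  before <- apply_qc(co, ann, probe_filter_first = TRUE)
  expect_identical(after$report$samples_dropped, before$report$samples_dropped)
  # probe fractions computed over retained samples can only keep more probes
  expect_gte(after$report$n_probes_kept, before$report$n_probes_kept)
})
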