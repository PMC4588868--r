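test_that("with no covariates the exposure coefficient is the difference of group means", {
  y <- c(0.50, 0.60, 0.55, 0.70, 0.80, 0.75)
  expo <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_probe_model(y, expo)
  expect_equal(fit$coefficient, mean(y[expo == 1]) - mean(y[expo == 0]))

  fx <- study_fixture()
  crude <- run_ewas(fx$cohort, proportions = NULL, covariates = character())
  expect_lt(max(abs(crude$coefficient - crude$raw_difference)), 1e-12)
})

test_that("an exact linear fit is guarded rather than producing NaN", {
  y <- c(0, 0, 1, 1)
  fit <- fit_probe_model(y, c(0, 0, 1, 1))
  expect_equal(fit$se, 0)
  expect_equal(fit$p, 0)
  fit0 <- fit_probe_model(rep(0.3, 4), c(0, 0, 1, 1))
  expect_equal(fit0$p, 1)
})

test_that("rank-deficient designs are refused with the aliased columns named", {
  err <- tryCatch(
    fit_probe_model(runif(6), c(0, 0, 0, 1, 1, 1),
                    covariates = tibble::tibble(dup = c(0, 0, 0, 1, 1, 1))),
    error = identity)
  expect_s3_class(err, "methmediate_invalid_argument")
  expect_match(conditionMessage(err), "dup")
})

test_that("fit_probe_model and the matrix EWAS path agree probe by probe", {
  fx <- study_fixture()
  ew <- run_ewas(fx$cohort, fx$props)
  covs <- fx$cohort$samples[, attr(ew, "covariates")]
  covs <- dplyr::bind_cols(covs, fx$props[match(fx$cohort$samples$sample_id,
                                                fx$props$sample_id), -1])
  for (pb in ew$probe_id[c(1, 50, 133)]) {
    single <- fit_probe_model(fx$cohort$beta[pb, ],
                              fx$cohort$samples$exposure, covs)
    row <- ew[ew$probe_id == pb, ]
    expect_equal(row$coefficient, single$coefficient, tolerance = 1e-10)
    expect_equal(row$se, single$se, tolerance = 1e-10)
    expect_equal(row$p, single$p, tolerance = 1e-10)
  }
})

test_that("the planted probe dominates the EWAS and its effect is recovered", {
  fx <- study_fixture()
  ew <- run_ewas(fx$cohort, fx$props)
  top <- ew[which.min(ew$p), ]
  expect_identical(top$probe_id, "cg09935388")
  expect_lt(abs(top$coefficient - (-0.105)), 2 * top$se)
  expect_true(top$q < 0.05)
  expect_true(abs(top$raw_difference) <= 1)
})

test_that("BH q-values match the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(1.0), 1.0)
  set.seed(101)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_brute_force(p), tolerance = 1e-12)
    # step-up q is monotone in the p ordering
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), class = "methmediate_invalid_argument")
  expect_error(bh_fdr(numeric()), class = "methmediate_invalid_argument")
})

test_that("EWAS output is invariant to probe and sample order", {
  fx <- study_fixture()
  ew <- run_ewas(fx$cohort, fx$props)
  perm_p <- sample(nrow(fx$cohort$beta))
  perm_s <- sample(ncol(fx$cohort$beta))
  shuf <- fx$cohort
  shuf$beta <- shuf$beta[perm_p, perm_s]
  shuf$detection_p <- shuf$detection_p[perm_p, perm_s]
  shuf$samples <- shuf$samples[perm_s, ]
  ew2 <- run_ewas(shuf, fx$props)
  ew2 <- ew2[match(ew$probe_id, ew2$probe_id), ]
  expect_equal(ew$coefficient, ew2$coefficient, tolerance = 1e-12)
  expect_equal(ew$p, ew2$p, tolerance = 1e-12)
  expect_equal(ew$q, ew2$q, tolerance = 1e-12)
})

test_that("null EWAS p-values are uniform and FDR control holds", {
  nf <- null_fixture()
  ew <- run_ewas(nf$cohort, nf$props)
  ks <- suppressWarnings(stats::ks.test(ew$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  frac05 <- mean(ew$p < 0.05)
  expect_lt(abs(frac05 - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(ew)))
  expect_equal(sum(ew$q < 0.05), 0)
})

test_that("cell-type correction changes the FDR list (sensitivity mode)", {
  fx <- study_fixture()
  with_cells <- run_ewas(fx$cohort, fx$props)
  without <- run_ewas(fx$cohort, NULL)
  expect_false(identical(with_cells$q, without$q))
  # composition confounding inflates the uncorrected small-p tail
  expect_gte(sum(without$p < 0.01), sum(with_cells$p < 0.01))
})

test_that("dose-response slopes are recovered and degenerate inputs refused", {
  ref <- simulate_reference(40, seed = 71, planted_probes = "cgDOSE")
  cfg <- sim_config(n_probes = 40, true_cpg_effects = c(cgDOSE = 0),
                    mediator_outcome_effects = numeric(),
                    missing_covariate_rate = 0, seed = 72)
  co <- simulate_cohort(cfg, ref)
  # plant a linear dose effect of 0.002 beta per cigarette on one probe
  expo <- co$samples$exposure == 1
  cigs <- co$samples$cigarettes_per_day[expo]
  co$beta["cgDOSE", expo] <- pmin(pmax(
    co$beta["cgDOSE", expo] + 0.002 * cigs, 0), 1)
  res <- dose_response_test(co, probe_ids = "cgDOSE",
                            covariates = c("sex", "gestational_age"))
  expect_lt(abs(res$slope - 0.002), 2 * res$se)
  expect_false(res$low_n)

  co2 <- co
  co2$samples$cigarettes_per_day[expo] <- 10
  expect_error(dose_response_test(co2, probe_ids = "cgDOSE",
                                  covariates = character()),
               class = "methmediate_invalid_argument")

  co3 <- co
  keep <- c(which(!expo), which(expo)[1:5])
  co3$beta <- co3$beta[, keep]
  co3$detection_p <- co3$detection_p[, keep]
  co3$samples <- co3$samples[keep, ]
  expect_warning(dose_response_test(co3, probe_ids = "cgDOSE",
                                    covariates = character()),
                 "low-n")
})

test_that("descriptive tables report group summaries, differences and tests", {
  sheet <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:8),
    exposure = rep(c(0, 1), each = 4),
    birthweight = c(3600, 3700, 3685, 3755, 3400, 3420, 3380, 3416),
    sex = c(0, 1, 0, 1, 0, 1, 1, 1),
    education = c(1, 1, 0, 1, 0, 0, 0, 1))
  tab <- descriptive_table(sheet, continuous = "birthweight",
                           categorical = c("sex", "education"))
  bw <- tab[tab$variable == "birthweight", ]
  expect_equal(bw$difference, mean(c(3400, 3420, 3380, 3416)) - 3685)
  expect_equal(bw$p_value,
               t.test(c(3400, 3420, 3380, 3416), c(3600, 3700, 3685, 3755),
                      var.equal = TRUE)$p.value)
  expect_true(all(c("sex", "education") %in% tab$variable))

  # identical groups: difference tests are non-significant by construction
  same <- sheet
  same$birthweight <- rep(c(3500, 3600, 3700, 3800), 2)
  tab2 <- descriptive_table(same, continuous = "birthweight",
                            categorical = character())
  expect_equal(tab2$difference, 0)
  expect_equal(tab2$p_value, 1)

  expect_error(descriptive_table(sheet[sheet$exposure == 1, ]),
               class = "methmediate_invalid_argument")
})
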