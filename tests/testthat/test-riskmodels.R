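test_that("the default enumeration contains exactly 30 risk equations", {
  cfg <- framework_config()
  expect_length(cfg$equations, 30)
  # every (outcome, state) the engine can visit resolves to one equation
  keys <- names(cfg$equations)
  expect_true(all(!duplicated(keys)))
  for (lot in 1:9) {
    expect_true(myelosim:::equation_key("bcr", lot) %in% keys)
    expect_true(myelosim:::equation_key("chemo_duration", lot,
                                        asct = lot == 1) %in% keys)
    if (lot < 9) expect_true(myelosim:::equation_key("tfi", lot) %in% keys)
  }
  # lines 6-9 share a single equation per outcome
  expect_identical(myelosim:::equation_key("bcr", 6),
                   myelosim:::equation_key("bcr", 9))
  expect_identical(myelosim:::equation_key("tfi", 7),
                   myelosim:::equation_key("tfi", 8))
})

test_that("the regimen catalog applies the 10% rule within a line", {
  n <- 20
  regs <- c(rep("VRd", 8), rep("VCd", 3), "Kd", rep("other", 8))
  patients <- data.frame(
    patient_id = sprintf("R%02d", 1:n), age_dx = 65, sex = "male",
    ecog = "0", iss = 1, paraprotein = 20, kappa_lc = 20, lambda_lc = 20,
    death_time = NA_real_, censor_time = 60, stringsAsFactors = FALSE)
  lines <- data.frame(
    patient_id = patients$patient_id, lot = 1L, regimen = regs,
    start_time = 1, end_time = 6, is_asct = FALSE, asct_planned = FALSE,
    maintenance = FALSE, bcr = NA_character_, dpp = 0, dkappa = 0,
    dlambda = 0, stringsAsFactors = FALSE)
  cat1 <- regimen_catalog(registry_table(patients, lines), 1)
  # VRd 40% and VCd 15% clear the threshold; Kd at 5% pools into "other"
  expect_identical(cat1, c("other", "VCd", "VRd"))
})

test_that("regimen catalogs pool rare regimens under the usage threshold", {
  reg <- small_registry()
  cat1 <- regimen_catalog(reg, 1)
  l1 <- reg$lines[!reg$lines$is_asct & reg$lines$lot %in% 1, ]
  for (lab in setdiff(cat1, "other")) {
    expect_gte(mean(l1$regimen == lab), 0.1)
  }
  expect_identical(cat1[1], "other")
})

test_that("estimation recovers ground-truth coefficients across equations", {
  cfg <- synth_config(n_patients = 5000, seed = 301,
                      missingness = list(ecog = 0, iss = 0, bcr_chemo = 0,
                                         bcr_asct = 0, end_date = 0))
  reg <- generate_registry(cfg)
  imp <- impute_registry(reg, imputation_spec(m = 2, seed = 3))
  mc <- suppressWarnings(estimate_all_equations(imp))
  truth <- ground_truth_coefficients()
  checked <- 0L; covered <- 0L
  for (key in c("os", "tt_first", "planned_asct", "dur_lot1_noasct",
                "dur_lot2", "tfi_lot1_noasct", "tfi_lot2", "bcr_lot1",
                "bcr_lot2", "maintenance_receipt")) {
    fit <- mc$equations[[key]]
    tr_eq <- truth$equations[[key]]
    tr_par <- if (tr_eq$family == "ologit") {
      c(tr_eq$beta, stats::setNames(tr_eq$ancillary$cutpoints,
                                    paste0("tau", seq_along(tr_eq$ancillary$cutpoints))))
    } else if (tr_eq$family == "gompertz") {
      c(tr_eq$beta, shape = tr_eq$ancillary$shape)
    } else if (tr_eq$family == "weibull") {
      c(tr_eq$beta, log_shape = log(tr_eq$ancillary$shape))
    } else tr_eq$beta
    pooled <- fit$pooled
    for (i in seq_len(nrow(pooled))) {
      tv <- tr_par[[pooled$term[i]]]
      if (is.null(tv) || is.na(tv)) next
      se <- sqrt(pooled$total_var[i])
      checked <- checked + 1L
      if (abs(pooled$estimate[i] - tv) < 1.96 * se) covered <- covered + 1L
    }
  }
  expect_gt(checked, 60)
  # nominal 95% coverage within Monte-Carlo slack
  expect_gte(covered / checked, 0.85)
})

test_that("fitted survival matches the Kaplan-Meier of its training data", {
  reg <- small_registry()
  imp <- impute_registry(reg, imputation_spec(m = 2, seed = 5))
  mc <- suppressWarnings(estimate_all_equations(imp))
  ds <- myelosim:::build_estimation_data(drop_unended_lines(imp[[1]]),
                                         mc$config)$dur_lot1_noasct
  km <- km_estimate(ds$time, ds$event)
  eq <- mc$equations$dur_lot1_noasct
  xbar <- colMeans(ds$X)
  dec <- stats::quantile(ds$time[ds$event == 1], seq(0.1, 0.9, 0.2))
  for (t in dec) {
    s_fit <- survival_value(t, eq, xbar)
    s_km <- km_at(km, t)
    expect_lt(abs(s_fit - s_km), 0.12)
  }
})

test_that("SD/PD induction patients are excluded from ASCT-receipt data", {
  reg <- small_registry()
  imp <- impute_registry(reg, imputation_spec(m = 2, seed = 7))
  tab <- drop_unended_lines(imp[[1]])
  cfg <- framework_config(regimen_catalog(tab, 1), regimen_catalog(tab, 2))
  ds <- myelosim:::build_estimation_data(tab, cfg)$asct_receipt
  # the collapsed previous-response covariate never indicates SD/PD (level 3)
  expect_true(all(ds$X[, "bcr_prev2"] %in% c(0, 1)))
  l1 <- tab$lines[!tab$lines$is_asct & tab$lines$lot %in% 1, ]
  n_sdpd <- sum(l1$asct_planned %in% TRUE & !is.na(l1$end_time) &
                  collapse_bcr(l1$bcr) %in% 3)
  n_elig <- sum(l1$asct_planned %in% TRUE & !is.na(l1$end_time) &
                  collapse_bcr(l1$bcr) %in% c(1, 2))
  expect_identical(nrow(ds$X), length(ds$y))
  expect_lte(length(ds$y), n_elig)
  expect_gt(n_sdpd, 0)  # the exclusion is actually exercised
})

test_that("estimation on a registry that never passes LoT 2 names the gap", {
  reg <- small_registry()
  l <- reg$lines[!is.na(reg$lines$lot) & reg$lines$lot <= 2 |
                   reg$lines$is_asct, ]
  reg2 <- registry_table(reg$patients, l)
  imp <- impute_registry(reg2, imputation_spec(m = 2, seed = 11))
  expect_error(suppressWarnings(estimate_all_equations(imp)), "dur_lot3")
})

test_that("pooled equations are invariant to imputation order", {
  reg <- small_registry()
  imp <- impute_registry(reg, imputation_spec(m = 3, seed = 13))
  m1 <- suppressWarnings(estimate_all_equations(imp))
  m2 <- suppressWarnings(estimate_all_equations(imp[c(3, 1, 2)]))
  expect_equal(m1$equations$os$beta, m2$equations$os$beta, tolerance = 1e-8)
  expect_equal(m1$equations$bcr_lot1$ancillary$cutpoints,
               m2$equations$bcr_lot1$ancillary$cutpoints, tolerance = 1e-8)
})

test_that("coefficient sets round-trip through JSON", {
  truth <- ground_truth_coefficients()
  path <- withr::local_tempfile(fileext = ".json")
  write_coefficients(truth, path)
  back <- read_coefficients(path)
  expect_identical(names(back$equations), names(truth$equations))
  for (key in names(truth$equations)) {
    expect_equal(back$equations[[key]]$beta, truth$equations[[key]]$beta)
    expect_identical(back$equations[[key]]$family,
                     truth$equations[[key]]$family)
  }
  expect_equal(back$curtailments, truth$curtailments)
  # a simulation from the re-read set reproduces the original exactly
  prof <- generate_cohort_at_diagnosis(synth_config(n_patients = 20, seed = 9),
                                       apply_missingness = FALSE)
  s1 <- cohort_summary(simulate_cohort(prof, truth,
                                       simulation_config(20, seed = 2)))
  s2 <- cohort_summary(simulate_cohort(prof, back,
                                       simulation_config(20, seed = 2)))
  expect_equal(s1, s2)
})
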