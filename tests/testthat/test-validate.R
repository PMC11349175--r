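test_that("the 70/30 split reproduces the published cohort sizes", {
  # 4,121 patients -> 2,884 training and 1,237 validation
  expect_identical(floor(0.7 * 4121), 2884)
  reg <- generate_registry(synth_config(n_patients = 4121, seed = 19,
                                        followup = c(30, 40)))
  parts <- split_cohort(reg, 0.7, seed = 2)
  expect_identical(n_patients(parts$train), 2884L)
  expect_identical(n_patients(parts$validation), 1237L)
  # all of a patient's lines travel with the patient, no leakage
  expect_length(intersect(parts$train$patients$patient_id,
                          parts$validation$patients$patient_id), 0)
  expect_setequal(c(parts$train$lines$patient_id,
                    parts$validation$lines$patient_id),
                  reg$lines$patient_id)
  # deterministic in the seed
  parts2 <- split_cohort(reg, 0.7, seed = 2)
  expect_identical(parts$train$patients$patient_id,
                   parts2$train$patients$patient_id)
})

test_that("a two-patient cohort splits one and one", {
  reg <- tiny_registry()
  reg2 <- registry_table(reg$patients[1:2, ],
                         reg$lines[reg$lines$patient_id %in% c("A", "B"), ])
  parts <- split_cohort(reg2, 0.5, seed = 1)
  expect_identical(n_patients(parts$train), 1L)
  expect_identical(n_patients(parts$validation), 1L)
  expect_error(split_cohort(registry_table(reg$patients[1, , drop = FALSE],
                                           reg$lines[0, ]), 0.5, 1),
               "at least 2")
})

test_that("the product-limit estimator matches the hand computation", {
  # times {2, 4+, 6}, events {1, 0, 1}:
  # S(2) = (1 - 1/3) = 2/3; at t = 4 censoring, no step;
  # S(6) = 2/3 * (1 - 1/1) = 0
  km <- km_estimate(c(2, 4, 6), c(1, 0, 1))
  expect_equal(km_at(km, 1.99), 1)
  expect_equal(km_at(km, 2), 2 / 3)
  expect_equal(km_at(km, 5.9), 2 / 3)
  expect_equal(km_at(km, 6), 0)
  # no censoring: one minus the empirical CDF
  tt <- c(1, 3, 3, 7, 9)
  km2 <- km_estimate(tt, rep(1, 5))
  for (t in c(0.5, 1, 2, 3, 8, 10)) {
    expect_equal(km_at(km2, t), mean(tt > t))
  }
  # all censored: survival stays at 1
  km3 <- km_estimate(c(5, 8, 13), c(0, 0, 0))
  expect_equal(km_at(km3, c(4, 9, 20)), c(1, 1, 1))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("monthly bootstrap p-values reproduce the worked examples", {
  expect_equal(monthly_pvalue(50, 100), 1)
  expect_equal(monthly_pvalue(5, 100), 0.1)
  expect_equal(monthly_pvalue(0, 100), 0)
  # symmetry and maximum at c = B/2
  for (c in c(0, 10, 33, 50)) {
    expect_equal(monthly_pvalue(c, 100), monthly_pvalue(100 - c, 100))
  }
  cs <- 0:100
  expect_identical(which.max(monthly_pvalue(cs, 100)), 51L)  # c = 50
  expect_true(all(monthly_pvalue(cs, 100) <= 1))
  expect_error(monthly_pvalue(101, 100), "\\[0, B\\]")
  expect_error(monthly_pvalue(1, 0), "at least 1")
})

test_that("overall survival by response summarizes categories correctly", {
  # degenerate: everyone dead at exactly 5 years in every category
  os <- data.frame(os_months = 60, event = 1L,
                   bcr_first = rep(bcr_levels(), each = 4),
                   stringsAsFactors = FALSE)
  tab <- os_by_bcr(os)
  expect_equal(tab$median_years, rep(5, 6))
  # all survivors at cutoff: median not reached, category kept
  os2 <- data.frame(os_months = 24, event = 0L, bcr_first = "CR",
                    stringsAsFactors = FALSE)
  tab2 <- os_by_bcr(os2)
  expect_true(is.na(tab2$median_years[tab2$bcr == "CR"]))
  expect_identical(tab2$n[tab2$bcr == "VGPR"], 0L)
  # uncensored quantiles agree with direct empirical quantiles
  set.seed(4)
  osm <- rweibull(400, 1.3, 80)
  os3 <- data.frame(os_months = osm, event = 1L, bcr_first = "PR",
                    stringsAsFactors = FALSE)
  tab3 <- os_by_bcr(os3)
  km <- km_estimate(osm, rep(1, 400))
  med <- min(km$time[km$surv <= 0.5]) / 12
  # agreement up to the width of one event step at the crossing
  expect_lt(abs(tab3$median_years[tab3$bcr == "PR"] - med), 0.05)
  expect_lt(abs(tab3$q25_years[tab3$bcr == "PR"] -
                  min(km$time[km$surv <= 0.75]) / 12), 0.05)
})

test_that("a tiny bootstrap validation run completes with full monthly output", {
  reg <- small_registry()
  rep <- suppressWarnings(
    bootstrap_validate(reg, imputation_spec(m = 2, seed = 3), B = 2,
                       n_sim = 150, seed = 7))
  expect_identical(nrow(rep$monthly), 120L)
  expect_true(all(rep$monthly$p >= 0 & rep$monthly$p <= 1))
  expect_true(all(rep$monthly$c >= 0 & rep$monthly$c <= 2))
  expect_gte(rep$pct_nonsignificant, 0)
  expect_lte(rep$pct_nonsignificant, 100)
  expect_identical(nrow(rep$os_by_bcr_simulated), 6L)
  expect_identical(nrow(rep$os_by_bcr_validation), 6L)
  # bands bracket their own point estimates
  expect_true(all(rep$monthly$val_lo <= rep$monthly$val_hi))
  expect_true(all(rep$monthly$sim_lo <= rep$monthly$sim_hi))
})

test_that("simulated survival orders by response when the truth is ordered", {
  truth <- ground_truth_coefficients()
  prof <- generate_cohort_at_diagnosis(synth_config(n_patients = 3000,
                                                    seed = 61),
                                       apply_missingness = FALSE)
  sm <- cohort_summary(simulate_cohort(prof, truth,
                                       simulation_config(3000, seed = 67)))
  tab <- os_by_bcr(data.frame(os_months = sm$os_months, event = 1L,
                              bcr_first = sm$bcr_first,
                              stringsAsFactors = FALSE))
  med <- tab$median_years
  # medians non-increasing from CR to PD within Monte-Carlo tolerance
  for (i in 1:5) {
    expect_gte(med[i], med[i + 1] - 0.75)
  }
  expect_gt(med[1], med[6])
})
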