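truth <- ground_truth_coefficients()

some_profiles <- function(n, seed = 17) {
  generate_cohort_at_diagnosis(synth_config(n_patients = n, seed = seed),
                               apply_missingness = FALSE)
}

test_that("cohort simulation is deterministic and order-independent", {
  prof <- some_profiles(30)
  cfgs <- simulation_config(30, seed = 44)
  a <- simulate_cohort(prof, truth, cfgs)
  b <- simulate_cohort(prof, truth, cfgs)
  expect_identical(cohort_summary(a), cohort_summary(b))
  # per-patient substreams: simulating any single row reproduces its
  # trajectory regardless of the other rows
  one <- with_seed(derive_seed(44, 104729, 7),
                   simulate_patient(prof[7, ], truth, cfgs))
  expect_equal(as.data.frame(a[[7]]), as.data.frame(one),
               ignore_attr = TRUE)
  expect_equal(attr(a[[7]], "os_months"), attr(one, "os_months"))
  expect_identical(simulate_cohort(prof[0, ], truth, cfgs), list())
})

test_that("every trajectory terminates, with strictly ordered events", {
  prof <- some_profiles(150)
  trs <- simulate_cohort(prof, truth, simulation_config(150, seed = 3))
  for (tr in trs) {
    expect_true(utils::tail(tr$event, 1) %in% c("death", "age_cap"))
    expect_true(all(diff(tr$time) >= 0))
    expect_true(all(tr$time <= attr(tr, "os_months") + 1e-9))
  }
})

test_that("durations and intervals never exceed the curtailment maxima", {
  prof <- some_profiles(200)
  trs <- simulate_cohort(prof, truth, simulation_config(200, seed = 5))
  lines <- trajectories_to_lines(trs)
  cm <- truth$curtailments
  chem <- lines[!lines$is_asct & !is.na(lines$end_time), ]
  dur <- chem$end_time - chem$start_time
  lim <- ifelse(chem$lot == 1,
                pmax(cm[["dur_lot1_asct"]], cm[["dur_lot1_noasct"]]),
                ifelse(chem$lot >= 6, cm[["dur_lot6_9"]],
                       cm[paste0("dur_lot", pmin(chem$lot, 5))]))
  expect_true(all(dur <= lim + 1e-9))
  asct <- lines[lines$is_asct & !is.na(lines$end_time), ]
  expect_true(all(asct$end_time - asct$start_time <= cm[["dur_asct"]] + 1e-9))
})

test_that("patients with SD/PD induction response are never transplanted", {
  prof <- some_profiles(400)
  trs <- simulate_cohort(prof, truth, simulation_config(400, seed = 6))
  lines <- trajectories_to_lines(trs)
  l1 <- lines[!lines$is_asct & lines$lot %in% 1, ]
  sdpd <- l1$patient_id[!is.na(l1$bcr) & l1$bcr %in% c("SD", "PD")]
  asct <- unique(lines$patient_id[lines$is_asct])
  expect_length(intersect(sdpd, asct), 0)
  # and some transplants do happen in this cohort
  expect_gt(length(asct), 0)
})

test_that("death during a line leaves the response unassessed", {
  prof <- some_profiles(300)
  trs <- simulate_cohort(prof, truth, simulation_config(300, seed = 7))
  for (tr in trs) {
    ln <- attr(tr, "lines")
    if (is.null(ln)) next
    # a line ending exactly at the terminal time had no response assessed
    at_death <- !is.na(ln$end_time) &
      abs(ln$end_time - attr(tr, "os_months")) < 1e-9
    # lot_end events only exist for assessed lines
    nbcr <- sum(tr$event == "bcr")
    expect_identical(nbcr, sum(!is.na(ln$bcr)))
    if (any(at_death & !ln$is_asct)) expect_true(all(is.na(ln$bcr[at_death])))
  }
})

test_that("survival beyond age 100 is curtailed at exactly the cap", {
  longlife <- truth
  longlife$equations$os$beta[["(Intercept)"]] <- -15  # essentially immortal
  prof <- data.frame(patient_id = "old", age_dx = 90, sex = "female",
                     ecog = "0", iss = 1, stringsAsFactors = FALSE)
  tr <- simulate_cohort(prof, longlife, simulation_config(1, seed = 1))[[1]]
  expect_identical(attr(tr, "terminal"), "age_cap")
  expect_equal(attr(tr, "os_months"), (100 - 90) * 12, tolerance = 1e-9)
})

test_that("maintenance lengthens only the LoT1 to LoT2 interval", {
  # force maintenance on/off through the receipt equation; the maintained
  # gap is drawn from its own duration clock
  always <- truth; never <- truth
  always$equations$maintenance_receipt$beta[["(Intercept)"]] <- 50
  never$equations$maintenance_receipt$beta[["(Intercept)"]] <- -50
  prof <- some_profiles(250, seed = 23)
  cfgs <- simulation_config(250, seed = 31)
  gap12 <- function(trs) {
    lines <- trajectories_to_lines(trs)
    chem <- lines[!lines$is_asct, ]
    l1 <- chem[chem$lot %in% 1, c("patient_id", "end_time")]
    la <- lines[lines$is_asct, c("patient_id", "end_time")]
    m <- match(l1$patient_id, la$patient_id)
    eff <- pmax(l1$end_time, ifelse(is.na(m), -Inf, la$end_time[m]), na.rm = TRUE)
    l2 <- chem[chem$lot %in% 2, c("patient_id", "start_time")]
    l2$start_time[match(l1$patient_id, l2$patient_id)] - eff
  }
  g_on <- gap12(simulate_cohort(prof, always, cfgs))
  g_off <- gap12(simulate_cohort(prof, never, cfgs))
  # maintained gaps come from the (longer) maintenance clock
  expect_gt(stats::median(g_on, na.rm = TRUE),
            stats::median(g_off, na.rm = TRUE))
  # maintenance events appear only between LoT 1 end and LoT 2 start
  trs <- simulate_cohort(prof, always, cfgs)
  for (tr in trs) {
    i <- which(tr$event == "maintenance_start")
    if (!length(i)) next
    starts <- tr$time[tr$event == "lot_start"]
    if (length(starts) >= 2) expect_lte(tr$time[i], starts[2])
    expect_gte(tr$time[i], starts[1])
  }
})

test_that("a more protective response coefficient increases median survival", {
  better <- truth
  better$equations$os$beta[["bcr_prev3"]] <- 2.0  # worse response far deadlier
  prof <- some_profiles(400, seed = 29)
  cfgs <- simulation_config(400, seed = 37)
  base_sm <- cohort_summary(simulate_cohort(prof, truth, cfgs))
  mod_sm <- cohort_summary(simulate_cohort(prof, better, cfgs))
  poor <- base_sm$bcr_first %in% c("SD", "PD")
  expect_lt(stats::median(mod_sm$os_months[mod_sm$bcr_first %in% c("SD", "PD")]),
            stats::median(base_sm$os_months[poor]))
})

test_that("response frequencies at a state converge to the ordered-logit law", {
  prof <- data.frame(patient_id = sprintf("q%d", 1:3000), age_dx = 58,
                     sex = "female", ecog = "1", iss = 2,
                     stringsAsFactors = FALSE)
  trs <- simulate_cohort(prof, truth, simulation_config(3000, seed = 41))
  lines <- trajectories_to_lines(trs)
  l1 <- lines[!lines$is_asct & lines$lot %in% 1 & !is.na(lines$bcr), ]
  sub <- l1[l1$regimen == "VCd", ]
  x <- c(age_dec = -0.7, male = 0, ecog1 = 1, ecog2plus = 0, iss2 = 1,
         iss3 = 0, "regimen:VRd" = 0, "regimen:VCd" = 1, "regimen:Rd" = 0)
  p <- category_probs(truth$equations$bcr_lot1, x)
  freq <- table(factor(sub$bcr, bcr_levels())) / nrow(sub)
  for (lev in bcr_levels()) {
    se <- sqrt(p[[lev]] * (1 - p[[lev]]) / nrow(sub))
    expect_lt(abs(freq[[lev]] - p[[lev]]), 4 * se + 0.01)
  }
})

test_that("the engine fast path reproduces the reference primitives", {
  cache <- myelosim:::build_engine_cache(truth)
  set.seed(53)
  x <- stats::setNames(rep(0, length(cache$terms)), cache$terms)
  x["age_dec"] <- 0.4; x["male"] <- 1; x["iss2"] <- 1
  x["bcr_prev2"] <- 1; x["lot_c"] <- 2
  for (key in c("os", "dur_lot2", "tfi_lot3", "dur_lot1_asct")) {
    eq <- truth$equations[[key]]
    ec <- cache$eqs[[key]]
    for (r in 1:20) {
      u <- runif(1, 0.01, 0.99)
      t0 <- if (key == "os") runif(1, 0, 60) else 0
      expect_equal(
        myelosim:::fast_cond_time(ec, myelosim:::fast_eta(ec, x), t0, u),
        conditional_event_time(eq, x, t0, u), tolerance = 1e-8)
    }
  }
  for (key in c("bcr_lot1", "bcr_lot6_9", "regimen_lot1")) {
    eq <- truth$equations[[key]]
    ec <- cache$eqs[[key]]
    for (r in seq(0.025, 0.975, by = 0.05)) {
      expect_identical(myelosim:::fast_cat(ec, x, r),
                       draw_categorical(eq, x, r))
    }
  }
})

test_that("a missing profile field is reported by name", {
  prof <- list(age_dx = 60, sex = "male", ecog = NA, iss = 1)
  expect_error(simulate_patient(prof, truth, simulation_config(1, seed = 1)),
               "ecog")
})
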