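# Synthetic registry generation: a cohort drawn to match published
# diagnosis-time marginals (age 67.3 +/- 11.6, 60.4% male, ECOG/ISS
# frequencies), pushed through the simulation engine under a known
# ground-truth coefficient set, converted to registry treatment rows, and
# degraded with realistic missingness (roughly 29% ECOG, 27% ISS, 27-29%
# best clinical response, 4% of chemotherapy end dates). Ground truth in,
# registry out: estimation, simulation, and validation are all testable
# against known parameters without access to confidential registry data.

#' Ground-truth risk-equation set for synthetic registries
#'
#' A complete, plausible coefficient set for the default 30-equation
#' framework: median overall survival near six years with a Gompertz hazard
#' (shape 0.012/month), Weibull treatment durations of four to six months,
#' treatment-free intervals that shorten with line number and worsen with
#' poorer response, response distributions that improve with better regimens
#' and transplant, and protective transplant effects. Coefficient signs
#' follow clinical direction (e.g. poorer best clinical response increases
#' the death hazard and shortens the next treatment-free interval).
#'
#' @param config a `framework_config`; its regimen catalogs must be the
#'   default ones
#' @return a `model_coefficients` object
#' @export
ground_truth_coefficients <- function(config = framework_config()) {
  defs <- config$equations
  nb <- function(...) {
    v <- c(...)
    stats::setNames(as.numeric(v), names(v))
  }
  mk_surv <- function(key, intercept, shape, effects = numeric(0),
                      family = defs[[key]]$family) {
    terms <- defs[[key]]$terms
    beta <- stats::setNames(rep(0, length(terms)), terms)
    beta[names(effects)] <- effects
    new_risk_equation(defs[[key]]$outcome, defs[[key]]$state, family,
                      beta = c("(Intercept)" = intercept, beta),
                      term_names = terms, ancillary = list(shape = shape))
  }
  mk_spline <- function(key, gamma, knots, effects = numeric(0)) {
    terms <- defs[[key]]$terms
    beta <- stats::setNames(rep(0, length(terms)), terms)
    beta[names(effects)] <- effects
    new_risk_equation(defs[[key]]$outcome, defs[[key]]$state,
                      "weibull_spline3", beta = beta, term_names = terms,
                      ancillary = list(knots = knots, gamma = gamma))
  }
  mk_logit <- function(key, intercept, effects = numeric(0)) {
    terms <- defs[[key]]$terms
    beta <- stats::setNames(rep(0, length(terms)), terms)
    beta[names(effects)] <- effects
    new_risk_equation(defs[[key]]$outcome, defs[[key]]$state, "logit",
                      beta = c("(Intercept)" = intercept, beta),
                      term_names = terms, ancillary = list())
  }
  mk_ologit <- function(key, cutpoints, effects = numeric(0)) {
    terms <- defs[[key]]$terms
    beta <- stats::setNames(rep(0, length(terms)), terms)
    beta[names(effects)] <- effects
    new_risk_equation(defs[[key]]$outcome, defs[[key]]$state, "ologit",
                      beta = beta, term_names = terms,
                      ancillary = list(cutpoints = cutpoints,
                                       levels = defs[[key]]$levels))
  }
  mk_mlogit <- function(key, coef) {
    terms <- defs[[key]]$terms
    levels <- defs[[key]]$levels
    colnames(coef) <- c("(Intercept)", terms)
    rownames(coef) <- levels[-1]
    par <- stats::setNames(as.vector(t(coef)),
                           paste(rep(rownames(coef), each = ncol(coef)),
                                 rep(colnames(coef), nrow(coef)), sep = ":"))
    new_risk_equation(defs[[key]]$outcome, defs[[key]]$state, "mlogit",
                      beta = par, term_names = terms,
                      ancillary = list(levels = levels, coef = coef))
  }
  bcr_fx <- function(p2, p3) nb(bcr_prev2 = p2, bcr_prev3 = p3)
  eqs <- list(
    os = mk_surv("os", -6.2, 0.012,
                 nb(age_dec = 0.35, male = 0.10, ecog1 = 0.25,
                    ecog2plus = 0.60, iss2 = 0.30, iss3 = 0.60, lot_c = 0.10,
                    bcr_prev2 = 0.35, bcr_prev3 = 0.80, post_asct = -0.25)),
    tt_first = mk_surv("tt_first", -0.89, 1.3,
                       nb(age_dec = -0.05, ecog1 = 0.05, ecog2plus = 0.10,
                          iss2 = 0.05, iss3 = 0.10)),
    planned_asct = mk_logit("planned_asct", 0.8,
                            nb(age_dec = -1.6, male = -0.2, ecog1 = -0.3,
                               ecog2plus = -1.0, iss2 = -0.2, iss3 = -0.4)),
    asct_receipt = mk_logit("asct_receipt", 2.2,
                            nb(age_dec = -0.3, male = -0.1,
                               bcr_prev2 = -0.4)),
    maintenance_receipt = mk_logit("maintenance_receipt", 0.1,
                                   nb(age_dec = -0.2, post_asct = 0.3)),
    regimen_lot1 = mk_mlogit("regimen_lot1", rbind(
      VRd = c(0.6, -0.5, 0.0, -0.1, -0.3),
      VCd = c(0.4, -0.1, 0.0, 0.0, -0.1),
      Rd = c(-0.2, 0.5, -0.1, 0.1, 0.2))),
    regimen_lot2 = mk_mlogit("regimen_lot2", rbind(
      Rd = c(0.5, 0.2, 0.0, 0.0, 0.1),
      DVd = c(0.3, -0.2, 0.0, 0.0, -0.1))),
    bcr_lot1 = mk_ologit("bcr_lot1", c(-1.73, -0.40, 0.85, 1.39, 2.20),
                         nb(age_dec = 0.15, male = 0.05, ecog1 = 0.20,
                            ecog2plus = 0.50, iss2 = 0.30, iss3 = 0.60,
                            "regimen:VRd" = -0.5, "regimen:VCd" = -0.3,
                            "regimen:Rd" = -0.1)),
    bcr_asct = mk_ologit("bcr_asct", c(-0.5, 0.9, 2.0, 2.6, 3.2),
                         nb(age_dec = 0.10, bcr_prev2 = 1.2)),
    bcr_lot2 = mk_ologit("bcr_lot2", c(-2.0, -0.6, 0.7, 1.3, 2.1),
                         c(nb(age_dec = 0.10, ecog1 = 0.15, ecog2plus = 0.40,
                              iss2 = 0.20, iss3 = 0.40),
                           bcr_fx(0.8, 1.6),
                           nb("regimen:Rd" = -0.2, "regimen:DVd" = -0.5))),
    bcr_lot3 = mk_ologit("bcr_lot3", c(-2.2, -0.8, 0.5, 1.1, 1.9),
                         c(nb(age_dec = 0.10, ecog2plus = 0.30, iss3 = 0.30),
                           bcr_fx(0.8, 1.6))),
    bcr_lot4 = mk_ologit("bcr_lot4", c(-0.3, 1.2),
                         c(nb(age_dec = 0.10), bcr_fx(0.8, 1.6))),
    bcr_lot5 = mk_ologit("bcr_lot5", c(-0.4, 1.1),
                         c(nb(age_dec = 0.10), bcr_fx(0.7, 1.4))),
    bcr_lot6_9 = mk_ologit("bcr_lot6_9", c(-0.5, 1.0),
                           c(bcr_fx(0.7, 1.4), nb(age_dec = 0.10,
                                                  lot_c = 0.10))),
    dur_lot1_asct = mk_spline(
      "dur_lot1_asct",
      gamma = c(-3.2, 1.8, 0.15, -0.10, 0.05),
      knots = log(c(0.5, 2.5, 4, 6, 18)),
      effects = nb(age_dec = 0.05)),
    dur_lot1_noasct = mk_surv("dur_lot1_noasct", -2.94, 1.6,
                              nb(age_dec = 0.05, ecog1 = 0.10,
                                 ecog2plus = 0.20, iss3 = 0.10,
                                 "regimen:VRd" = -0.10, "regimen:Rd" = -0.30)),
    dur_lot2 = mk_surv("dur_lot2", -2.87, 1.4,
                       nb(age_dec = 0.05, iss3 = 0.10, "regimen:Rd" = -0.30,
                          "regimen:DVd" = -0.20)),
    dur_lot3 = mk_surv("dur_lot3", -2.58, 1.3,
                       nb(age_dec = 0.05, ecog2plus = 0.15)),
    dur_lot4 = mk_surv("dur_lot4", -2.46, 1.3, nb(age_dec = 0.05)),
    dur_lot5 = mk_surv("dur_lot5", -2.17, 1.2, nb(age_dec = 0.05)),
    dur_lot6_9 = mk_surv("dur_lot6_9", -2.03, 1.2, nb(lot_c = 0.05)),
    dur_asct = mk_surv("dur_asct", -0.82, 2.5, nb(age_dec = 0.05)),
    tfi_lot1_asct = mk_surv("tfi_lot1_asct", -3.39, 0.95,
                            c(nb(age_dec = -0.05, male = 0.05),
                              bcr_fx(0.4, 1.0))),
    tfi_lot1_noasct = mk_surv("tfi_lot1_noasct", -2.74, 0.9,
                              c(nb(age_dec = -0.05, male = 0.05),
                                bcr_fx(0.4, 1.0))),
    tfi_lot2 = mk_surv("tfi_lot2", -2.44, 0.9,
                       c(nb(age_dec = -0.05), bcr_fx(0.4, 0.9))),
    tfi_lot3 = mk_surv("tfi_lot3", -2.24, 0.9,
                       c(nb(age_dec = -0.05), bcr_fx(0.4, 0.9))),
    tfi_lot4 = mk_surv("tfi_lot4", -2.12, 0.9,
                       c(nb(age_dec = -0.05), bcr_fx(0.3, 0.8))),
    tfi_lot5 = mk_surv("tfi_lot5", -1.98, 0.9,
                       nb(age_dec = -0.05, bcr_prev2 = 0.3)),
    tfi_lot6_9 = mk_surv("tfi_lot6_9", -1.82, 0.9,
                         c(nb(age_dec = -0.05, lot_c = 0.05),
                           bcr_fx(0.3, 0.7))),
    dur_maintenance = mk_surv("dur_maintenance", -3.77, 1.0,
                              c(bcr_fx(0.3, 0.8), nb(post_asct = -0.2)))
  )
  curtail <- c(tt_first = 24, dur_lot1_asct = 12, dur_lot1_noasct = 36,
               dur_lot2 = 36, dur_lot3 = 36, dur_lot4 = 36, dur_lot5 = 30,
               dur_lot6_9 = 30, dur_asct = 6, tfi_lot1_asct = 150,
               tfi_lot1_noasct = 150, tfi_lot2 = 120, tfi_lot3 = 120,
               tfi_lot4 = 96, tfi_lot5 = 96, tfi_lot6_9 = 96,
               dur_maintenance = 120)
  model_coefficients(eqs, curtail, config)
}

#' Synthetic-registry configuration
#'
#' Defaults reproduce the emulated registry's published diagnosis-time
#' marginals and missingness: age 67.3 +/- 11.6 (truncated to 18-100), 60.4%
#' male, ECOG 0/1/2plus at 42.9/36.9/20.2% among non-missing, ISS 1/2/3 at
#' 29.3/41.7/29.0%; missing fractions 29% ECOG, 27% ISS, 29% response to
#' chemotherapy, 26.6% response to transplant, and 4% of completed
#' chemotherapy lines losing their end date. Follow-up is administratively
#' censored uniformly over a 0.5 to 14.5-year accrual window.
#'
#' @param n_patients cohort size
#' @param seed integer master seed
#' @param ground_truth `model_coefficients` generating the trajectories
#' @param missingness named list of missing fractions (`ecog`, `iss`,
#'   `bcr_chemo`, `bcr_asct`, `end_date`), all in \[0, 1\]
#' @param table1 named list of marginal targets (`age_mean`, `age_sd`,
#'   `p_male`, `ecog_probs`, `iss_probs`)
#' @param followup length-2 vector: uniform range (months) of administrative
#'   censoring times
#' @return object of class `synth_config`
#' @export
synth_config <- function(n_patients = 4121, seed = 1,
                         ground_truth = ground_truth_coefficients(),
                         missingness = list(ecog = 0.29, iss = 0.27,
                                            bcr_chemo = 0.29,
                                            bcr_asct = 0.266,
                                            end_date = 0.04),
                         table1 = list(age_mean = 67.3, age_sd = 11.6,
                                       p_male = 0.604,
                                       ecog_probs = c(0.429, 0.369, 0.202),
                                       iss_probs = c(0.293, 0.417, 0.290)),
                         followup = c(6, 174)) {
  stopifnot(n_patients >= 1,
            all(unlist(missingness) >= 0), all(unlist(missingness) <= 1))
  structure(list(n_patients = n_patients, seed = seed,
                 ground_truth = ground_truth, missingness = missingness,
                 table1 = table1, followup = followup),
            class = "synth_config")
}

# MAR missingness mask whose probability depends on observed age: logistic
# in age with slope 0.25/decade, intercept calibrated so the realized mean
# equals the target fraction.
mar_mask <- function(frac, age_dec) {
  if (frac <= 0) return(rep(FALSE, length(age_dec)))
  if (frac >= 1) return(rep(TRUE, length(age_dec)))
  a <- stats::uniroot(function(a) mean(stats::plogis(a + 0.25 * age_dec)) - frac,
                      c(-20, 20))$root
  stats::runif(length(age_dec)) < stats::plogis(a + 0.25 * age_dec)
}

#' Generate a synthetic cohort at diagnosis
#'
#' Draws fully observed diagnostic profiles (truncated-normal age, Bernoulli
#' sex, categorical ECOG/ISS, log-normal paraprotein and free light chains),
#' then optionally applies missing-at-random masking of ECOG and ISS whose
#' probability depends on observed age only.
#'
#' @param config a `synth_config`
#' @param apply_missingness mask ECOG/ISS per `config$missingness`?
#' @return data frame of `PatientRecord` fields (death and censoring empty;
#'   those come from [generate_registry()])
#' @export
generate_cohort_at_diagnosis <- function(config, apply_missingness = TRUE) {
  with_seed(derive_seed(config$seed, 1), {
    n <- config$n_patients
    t1 <- config$table1
    # inverse-CDF truncated normal on [18, 100]
    plo <- stats::pnorm(18, t1$age_mean, t1$age_sd)
    phi <- stats::pnorm(100, t1$age_mean, t1$age_sd)
    age <- stats::qnorm(stats::runif(n, plo, phi), t1$age_mean, t1$age_sd)
    p <- data.frame(
      patient_id = sprintf("P%05d", seq_len(n)),
      age_dx = age,
      sex = ifelse(stats::runif(n) < t1$p_male, "male", "female"),
      ecog = sample(c("0", "1", "2plus"), n, TRUE, prob = t1$ecog_probs),
      iss = sample(1:3, n, TRUE, prob = t1$iss_probs),
      paraprotein = stats::rlnorm(n, log(25), 0.6),
      kappa_lc = stats::rlnorm(n, log(30), 0.9),
      lambda_lc = stats::rlnorm(n, log(25), 0.9),
      death_time = NA_real_,
      censor_time = NA_real_,
      stringsAsFactors = FALSE)
    if (apply_missingness) {
      age_dec <- (p$age_dx - 65) / 10
      p$ecog[mar_mask(config$missingness$ecog %||% 0, age_dec)] <- NA
      p$iss[mar_mask(config$missingness$iss %||% 0, age_dec)] <- NA
    }
    p
  })
}

# mean log-ratio change in paraprotein by true 6-level response; the
# laboratory signal that makes missing response imputable
bcr_lab_means <- function() c(CR = -3.0, VGPR = -2.2, PR = -1.4, MR = -0.7,
                              SD = -0.15, PD = 0.5)

#' Generate a full synthetic registry with known ground truth
#'
#' Simulates every patient's complete trajectory under the ground-truth
#' coefficients, converts it to treatment rows, draws within-line laboratory
#' changes that encode the true response plus noise, applies administrative
#' censoring uniform over the accrual window, and injects the configured
#' missingness. The true (pre-masking) patient characteristics, responses
#' and death times are attached as attribute `"truth"` for parameter- and
#' imputation-recovery checks.
#'
#' @param config a `synth_config`
#' @return a `registry_table` (attribute `"truth"`: list with complete
#'   `patients` and per-line true `bcr`)
#' @export
generate_registry <- function(config) {
  truth <- config$ground_truth
  cohort <- generate_cohort_at_diagnosis(config, apply_missingness = FALSE)
  sim_cfg <- simulation_config(n_patients = config$n_patients,
                               seed = derive_seed(config$seed, 2))
  trajs <- simulate_cohort(cohort, truth, sim_cfg)
  sm <- cohort_summary(trajs)
  lines <- trajectories_to_lines(trajs)
  with_seed(derive_seed(config$seed, 3), {
    # laboratory changes from true response (interim labs for unassessed lines)
    nl <- nrow(lines)
    latent <- lines$bcr
    latent[is.na(latent)] <- sample(bcr_levels(), sum(is.na(latent)), TRUE,
                                    prob = c(.15, .25, .30, .10, .10, .10))
    mu <- bcr_lab_means()[latent]
    lines$dpp <- stats::rnorm(nl, mu, 0.7)
    lines$dkappa <- stats::rnorm(nl, 0.8 * mu, 1.0)
    lines$dlambda <- stats::rnorm(nl, 0.8 * mu, 1.0)

    # administrative censoring
    cutoff <- stats::runif(config$n_patients, config$followup[1],
                           config$followup[2])
    died <- sm$os_months <= cutoff
    patients <- cohort
    patients$death_time <- ifelse(died, sm$os_months, NA)
    patients$censor_time <- ifelse(died, sm$os_months, cutoff)
    cut_l <- cutoff[match(lines$patient_id, patients$patient_id)]
    keep <- lines$start_time < cut_l
    lines <- lines[keep, , drop = FALSE]
    cut_l <- cut_l[keep]
    ongoing <- !is.na(lines$end_time) & lines$end_time > cut_l
    lines$end_time[ongoing] <- NA
    lines$bcr[ongoing] <- NA
    bcr_true <- lines$bcr  # after censoring, before missingness masks

    # missingness injection
    age_dec <- (patients$age_dx - 65) / 10
    patients$ecog[mar_mask(config$missingness$ecog %||% 0, age_dec)] <- NA
    patients$iss[mar_mask(config$missingness$iss %||% 0, age_dec)] <- NA
    chem <- !lines$is_asct
    obs_bcr <- !is.na(lines$bcr)
    m_chemo <- config$missingness$bcr_chemo %||% 0
    m_asct <- config$missingness$bcr_asct %||% 0
    lines$bcr[chem & obs_bcr &
                stats::runif(nrow(lines)) < m_chemo] <- NA
    lines$bcr[!chem & obs_bcr &
                stats::runif(nrow(lines)) < m_asct] <- NA
    complete_end <- chem & !is.na(lines$end_time)
    lines$end_time[complete_end &
                     stats::runif(nrow(lines)) <
                       (config$missingness$end_date %||% 0)] <- NA

    out <- registry_table(patients, lines)
    attr(out, "truth") <- list(patients = cohort, death = sm,
                               lines_bcr = bcr_true)
    out
  })
}
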