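# Out-of-sample validation: 70/30 cohort split, bootstrap pipeline
# (separate imputation, estimation and simulation per bootstrap), monthly
# two-sided bootstrap p-values comparing observed and simulated overall
# survival, pointwise percentile bands, and the response-surrogacy summary
# (overall survival by best clinical response to first treatment).

#' Split a registry into training and validation cohorts
#'
#' Patient-level random partition without replacement; the training cohort
#' receives `floor(train_fraction * N)` patients and every patient's
#' treatment rows travel with the patient.
#'
#' @param table a `registry_table`
#' @param train_fraction fraction in (0, 1), default 0.7
#' @param seed integer seed
#' @return list with elements `train` and `validation`
#' @export
split_cohort <- function(table, train_fraction = 0.7, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_("train_fraction must lie strictly in (0, 1)")
  N <- nrow(table$patients)
  if (N < 2) stop_("need at least 2 patients to split")
  n_train <- floor(train_fraction * N)
  idx <- with_seed(seed, sample.int(N, n_train))
  subset_registry <- function(keep) {
    p <- table$patients[keep, , drop = FALSE]
    l <- table$lines[table$lines$patient_id %in% p$patient_id, , drop = FALSE]
    rownames(p) <- rownames(l) <- NULL
    registry_table(p, l)
  }
  train <- subset_registry(sort(idx))
  validation <- subset_registry(setdiff(seq_len(N), idx))
  list(train = train, validation = validation)
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function; censored observations
#' leave the risk set without producing a step.
#'
#' @param times non-negative event/censoring times
#' @param events 1 = event, 0 = censored
#' @return object of class `km_curve`: data frame of `time`, `surv`,
#'   `n_risk`, `n_event`
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop_("empty input to km_estimate")
  if (any(times < 0)) stop_("times must be non-negative")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(data.frame(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                       n_event = sf$n.event),
            class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step convention: S(t) is the estimate after all events
#' at or before `t`; 1 before the first time point, and the last value
#' carried beyond the end of follow-up.
#'
#' @param km a `km_curve`
#' @param t times to evaluate at
#' @return survival probabilities
#' @export
km_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  c(1, km$surv)[idx + 1]
}

#' Monthly two-sided bootstrap p-value
#'
#' Under the null that the two survival curves are equal, the count `c` of
#' bootstrap replicates in which validation-cohort survival exceeds
#' simulated-cohort survival is binomial(B, 1/2); the two-sided sign
#' p-value is `min(1, 2 * min(c, B - c) / B)`. Symmetric in `c` and `B - c`
#' and maximal (1) at `c = B/2`.
#'
#' @param c count of bootstraps with validation survival above simulated
#'   survival (may be fractional when ties are split)
#' @param B total number of bootstraps
#' @return p-value in \[0, 1\] (vectorized over `c`)
#' @export
monthly_pvalue <- function(c, B) {
  if (B < 1) stop_("B must be at least 1")
  if (any(c < 0) || any(c > B)) stop_("c must lie in [0, B]")
  pmin(1, 2 * pmin(c, B - c) / B)
}

#' Overall survival by best clinical response to first treatment
#'
#' Median and quartile overall survival (years) per 6-level response
#' category — response to LoT 1 for non-transplanted patients and to ASCT
#' for transplanted patients. Quantiles come from the Kaplan-Meier estimate,
#' so censoring is respected; a quantile beyond follow-up is reported as
#' `NA` ("not reached"). Empty categories are kept with `n = 0`.
#'
#' @param os data frame with columns `os_months`, `event`, `bcr_first`
#'   (or a list of trajectories, which is summarized first)
#' @return data frame: `bcr`, `n`, `median_years`, `q25_years`, `q75_years`
#' @export
os_by_bcr <- function(os) {
  if (is.list(os) && !is.data.frame(os)) {
    sm <- cohort_summary(os)
    os <- data.frame(os_months = sm$os_months, event = 1L,
                     bcr_first = sm$bcr_first, stringsAsFactors = FALSE)
  }
  res <- lapply(bcr_levels(), function(lev) {
    sub <- os[!is.na(os$bcr_first) & os$bcr_first == lev, , drop = FALSE]
    if (!nrow(sub)) {
      return(data.frame(bcr = lev, n = 0L, median_years = NA_real_,
                        q25_years = NA_real_, q75_years = NA_real_))
    }
    sf <- survival::survfit(survival::Surv(sub$os_months, sub$event) ~ 1)
    q <- stats::quantile(sf, probs = c(0.25, 0.5, 0.75))$quantile / 12
    data.frame(bcr = lev, n = nrow(sub), median_years = unname(q[2]),
               q25_years = unname(q[1]), q75_years = unname(q[3]))
  })
  do.call(rbind, res)
}

registry_os <- function(table) {
  p <- table$patients
  data.frame(patient_id = p$patient_id, os_months = p$censor_time,
             event = as.integer(!is.na(p$death_time)),
             stringsAsFactors = FALSE)
}

# response to LoT 1 / ASCT for registry patients (ASCT response where
# transplanted, induction response otherwise)
registry_bcr_first <- function(table) {
  l <- table$lines
  l1 <- l[!l$is_asct & !is.na(l$lot) & l$lot == 1, c("patient_id", "bcr")]
  la <- l[l$is_asct, c("patient_id", "bcr")]
  bcr <- l1$bcr[match(table$patients$patient_id, l1$patient_id)]
  ma <- match(table$patients$patient_id, la$patient_id)
  bcr[!is.na(ma)] <- la$bcr[ma[!is.na(ma)]]
  bcr
}

#' Bootstrap out-of-sample validation
#'
#' Splits the registry 70/30 into training and validation cohorts, then runs
#' `B` bootstrap replicates: resample the training cohort with replacement,
#' multiply impute it, estimate all risk equations with Rubin's-rules
#' pooling, simulate `n_sim` patients whose diagnostic profiles are drawn
#' (with replacement) from the imputed validation cohort, and read monthly
#' overall survival for the (resampled) validation cohort and the simulated
#' cohort off their Kaplan-Meier curves. Per month, `c` counts bootstraps
#' with validation survival strictly above simulated survival (exact ties
#' count 1/2), giving the two-sided bootstrap sign p-value; 95% bands are
#' pointwise 2.5/97.5 percentiles across bootstraps.
#'
#' @param registry a `registry_table`
#' @param spec an [imputation_spec()]
#' @param B number of bootstrap replicates (default 100)
#' @param n_sim simulated patients per bootstrap (default 10000)
#' @param months month grid for the comparison (default 1:120)
#' @param train_fraction training share (default 0.7)
#' @param seed master seed
#' @param cfg optional `framework_config`; defaults to catalogs from the
#'   training cohort under the 10% regimen rule
#' @param progress print per-bootstrap progress lines?
#' @return object of class `validation_report`: list with `monthly` (month,
#'   c, p, band columns), `pct_nonsignificant` (share of months with
#'   p >= 0.05, in percent), `os_by_bcr_validation`, `os_by_bcr_simulated`,
#'   `B`, `n_sim`, `seed`
#' @export
bootstrap_validate <- function(registry, spec = imputation_spec(), B = 100,
                               n_sim = 10000, months = 1:120,
                               train_fraction = 0.7, seed = 1, cfg = NULL,
                               progress = FALSE) {
  if (B < 2) stop_("B must be at least 2")
  registry <- drop_unended_lines(registry)
  parts <- split_cohort(registry, train_fraction, seed = derive_seed(seed, 11))
  train <- parts$train
  val <- parts$validation
  if (is.null(cfg)) {
    cfg <- framework_config(lot1_catalog = regimen_catalog(train, 1),
                            lot2_catalog = regimen_catalog(train, 2))
  }
  val_spec <- spec; val_spec$seed <- derive_seed(seed, 12)
  val_imp <- impute_registry(val, val_spec)
  val_os <- registry_os(val)
  nv <- nrow(val$patients)
  val_S <- matrix(NA_real_, B, length(months))
  sim_S <- matrix(NA_real_, B, length(months))
  sim_os_acc <- vector("list", B)
  for (b in seq_len(B)) {
    stage <- "resample training cohort"
    res <- tryCatch({
      idx <- with_seed(derive_seed(seed, 13, b),
                       sample.int(nrow(train$patients), replace = TRUE))
      tr_b <- resample_registry(train, idx)
      stage <- "multiple imputation"
      spec_b <- spec; spec_b$seed <- derive_seed(seed, 14, b)
      imp_b <- impute_registry(tr_b, spec_b)
      stage <- "risk-equation estimation"
      mc_b <- suppressWarnings(estimate_all_equations(imp_b, cfg))
      stage <- "simulation"
      vimp <- val_imp[[(b - 1) %% length(val_imp) + 1]]
      pidx <- with_seed(derive_seed(seed, 15, b),
                        sample.int(nv, n_sim, replace = TRUE))
      profiles <- vimp$patients[pidx, c("patient_id", "age_dx", "sex",
                                        "ecog", "iss")]
      sim <- simulate_cohort(profiles, mc_b,
                             simulation_config(n_sim,
                                               seed = derive_seed(seed, 16, b)))
      sm <- cohort_summary(sim)
      stage <- "survival comparison"
      vidx <- with_seed(derive_seed(seed, 17, b),
                        sample.int(nv, replace = TRUE))
      km_v <- km_estimate(val_os$os_months[vidx], val_os$event[vidx])
      km_s <- km_estimate(sm$os_months, rep(1L, nrow(sm)))
      list(vS = km_at(km_v, months), sS = km_at(km_s, months),
           os = data.frame(os_months = sm$os_months, event = 1L,
                           bcr_first = sm$bcr_first,
                           stringsAsFactors = FALSE))
    }, error = function(e) {
      stop_("bootstrap %d failed at stage '%s': %s", b, stage,
            conditionMessage(e))
    })
    val_S[b, ] <- res$vS
    sim_S[b, ] <- res$sS
    sim_os_acc[[b]] <- res$os
    if (progress)
      message(sprintf("bootstrap %d/%d done", b, B))
  }
  cc <- colSums(val_S > sim_S) + 0.5 * colSums(val_S == sim_S)
  pv <- monthly_pvalue(cc, B)
  monthly <- data.frame(
    month = months, c = cc, p = pv,
    val_lo = apply(val_S, 2, stats::quantile, 0.025),
    val_hi = apply(val_S, 2, stats::quantile, 0.975),
    sim_lo = apply(sim_S, 2, stats::quantile, 0.025),
    sim_hi = apply(sim_S, 2, stats::quantile, 0.975))
  sim_os_all <- do.call(rbind, sim_os_acc)
  val_bcr <- data.frame(os_months = val_os$os_months, event = val_os$event,
                        bcr_first = registry_bcr_first(val_imp[[1]]),
                        stringsAsFactors = FALSE)
  structure(list(monthly = monthly,
                 pct_nonsignificant = 100 * mean(pv >= 0.05),
                 os_by_bcr_validation = os_by_bcr(val_bcr),
                 os_by_bcr_simulated = os_by_bcr(sim_os_all),
                 B = B, n_sim = n_sim, seed = seed),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> B = %d bootstraps, %d simulated patients each\n",
    x$B, x$n_sim))
  cat(sprintf("  months non-significant (p >= 0.05): %.1f%%\n",
              x$pct_nonsignificant))
  cat("  overall survival by response (simulated cohort, years):\n")
  print(x$os_by_bcr_simulated, row.names = FALSE)
  invisible(x)
}

# bootstrap resample of a registry's patients (duplicates get fresh ids so
# referential integrity holds)
resample_registry <- function(table, idx) {
  p <- table$patients[idx, , drop = FALSE]
  old_id <- p$patient_id
  p$patient_id <- sprintf("%s.%d", old_id, seq_along(idx))
  lsplit <- split(seq_len(nrow(table$lines)), table$lines$patient_id)
  pick <- lsplit[old_id]
  reps <- lengths(pick)
  li <- unlist(pick, use.names = FALSE)
  l <- table$lines[li, , drop = FALSE]
  l$patient_id <- rep(p$patient_id, reps)
  rownames(p) <- rownames(l) <- NULL
  registry_table(p, l)
}
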