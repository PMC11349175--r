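# Building estimation datasets from a completed (post-imputation) registry
# and fitting + pooling the full risk-equation set.
#
# The overall-survival equation is fitted on health-state entry episodes
# (left-truncated counting-process rows) so that one equation, re-evaluated
# with updated line number / response / transplant covariates, is exactly
# the model the engine re-draws from at each state entry.

reg_map <- function(regimen, catalog) {
  ifelse(regimen %in% catalog, regimen, "other")
}

# chronological per-row derived fields for an ordered lines table
line_derived <- function(l) {
  n <- nrow(l)
  first <- !duplicated(l$patient_id)
  bcr3 <- collapse_bcr(l$bcr)
  prev_bcr3 <- c(NA, bcr3[-n]); prev_bcr3[first] <- NA
  prev_asct_end <- c(FALSE, (l$is_asct & !is.na(l$end_time))[-n])
  post_asct <- stats::ave(as.numeric(prev_asct_end), l$patient_id,
                          FUN = cummax) > 0
  post_asct[first] <- FALSE
  nxt_same <- c(l$patient_id[-1], NA) == l$patient_id
  list(bcr3 = bcr3, prev_bcr3 = prev_bcr3, post_asct = post_asct,
       first = first, nxt_same = !is.na(nxt_same) & nxt_same)
}

surv_ds <- function(time, event, ctx, terms, tstart = NULL) {
  list(kind = "surv", time = pmax(time, 1e-6), event = as.integer(event),
       X = term_columns(ctx, terms), tstart = tstart)
}
disc_ds <- function(y, ctx, terms) {
  list(kind = "disc", y = y, X = term_columns(ctx, terms))
}

line_ctx <- function(p, l, idx, lot = NULL, bcr_prev = NULL,
                     post_asct = NULL, regimen = NULL) {
  m <- match(l$patient_id[idx], p$patient_id)
  list(age_dx = p$age_dx[m], sex = p$sex[m], ecog = p$ecog[m],
       iss = p$iss[m],
       lot = lot %||% l$lot[idx],
       bcr_prev = bcr_prev %||% rep(0, length(idx)),
       post_asct = post_asct %||% rep(FALSE, length(idx)),
       regimen = regimen %||% rep("other", length(idx)))
}

# Assemble every equation's estimation dataset from one completed registry.
build_estimation_data <- function(table, cfg) {
  p <- table$patients
  l <- table$lines[order(table$lines$patient_id, table$lines$start_time), ,
                   drop = FALSE]
  rownames(l) <- NULL
  d <- if (nrow(l)) line_derived(l) else NULL
  defs <- cfg$equations
  out <- list()
  terms_of <- function(key) defs[[key]]$terms
  censor <- p$censor_time[match(l$patient_id, p$patient_id)]
  died <- !is.na(p$death_time)
  chem <- !l$is_asct

  # --- overall survival: state-entry episodes -----------------------------
  ev <- rbind(
    data.frame(pid = l$patient_id, t = l$start_time,
               lot_up = ifelse(chem, l$lot, NA), bcr_up = NA,
               asct_up = FALSE),
    {
      e <- !is.na(l$end_time)
      data.frame(pid = l$patient_id[e], t = l$end_time[e],
                 lot_up = NA, bcr_up = d$bcr3[e],
                 asct_up = l$is_asct[e])
    })
  ev <- rbind(data.frame(pid = p$patient_id, t = 0, lot_up = 0, bcr_up = NA,
                         asct_up = FALSE), ev)
  ev <- ev[order(ev$pid, ev$t), , drop = FALSE]
  lot_st <- stats::ave(ifelse(is.na(ev$lot_up), 0, ev$lot_up), ev$pid,
                       FUN = cummax)
  # carry the most recent response forward (ev is sorted by pid, time, so
  # tapply groups concatenate back in row order)
  bcr_st <- unlist(tapply(ev$bcr_up, ev$pid, function(z) {
    z[1] <- 0
    for (i in seq_along(z)[-1]) if (is.na(z[i])) z[i] <- z[i - 1]
    z
  }, simplify = FALSE), use.names = FALSE)
  asct_st <- stats::ave(as.numeric(ev$asct_up), ev$pid, FUN = cummax) > 0
  last <- !duplicated(ev$pid, fromLast = TRUE)
  cen <- p$censor_time[match(ev$pid, p$patient_id)]
  tstop <- c(ev$t[-1], NA)
  tstop[last] <- cen[last]
  keep <- tstop > ev$t & ev$t < cen
  tstop <- pmin(tstop, cen)
  died_ev <- died[match(ev$pid, p$patient_id)]
  m <- match(ev$pid, p$patient_id)
  ctx <- list(age_dx = p$age_dx[m], sex = p$sex[m], ecog = p$ecog[m],
              iss = p$iss[m], lot = lot_st, bcr_prev = bcr_st,
              post_asct = asct_st, regimen = rep("other", nrow(ev)))
  ctx <- lapply(ctx, function(v) v[keep])
  # the death lands on the patient's last *kept* episode (an event recorded
  # exactly at the end of follow-up, e.g. a line ending at death, has no
  # episode of its own)
  pid_k <- ev$pid[keep]
  last_k <- !duplicated(pid_k, fromLast = TRUE)
  out$os <- surv_ds(time = tstop[keep], event = last_k & died_ev[keep],
                    ctx = ctx, terms = terms_of("os"),
                    tstart = pmax(ev$t[keep], 0))

  # --- time from diagnosis to first treatment -----------------------------
  fl <- l[chem & !is.na(l$lot) & l$lot == 1, , drop = FALSE]
  mfirst <- match(p$patient_id, fl$patient_id)
  t1 <- fl$start_time[mfirst]
  has1 <- !is.na(t1)
  ctx0 <- list(age_dx = p$age_dx, sex = p$sex, ecog = p$ecog, iss = p$iss,
               lot = rep(0, nrow(p)), bcr_prev = rep(0, nrow(p)),
               post_asct = rep(FALSE, nrow(p)), regimen = rep("other", nrow(p)))
  out$tt_first <- surv_ds(time = ifelse(has1, t1, p$censor_time),
                          event = has1, ctx = ctx0,
                          terms = terms_of("tt_first"))

  # --- LoT-1 decision logits ----------------------------------------------
  i1 <- which(chem & !is.na(l$lot) & l$lot == 1)
  if (length(i1)) {
    ctx1 <- line_ctx(p, l, i1, lot = rep(1, length(i1)))
    out$planned_asct <- disc_ds(as.integer(l$asct_planned[i1]), ctx1,
                                terms_of("planned_asct"))
    has_asct <- l$patient_id[i1] %in% l$patient_id[l$is_asct]
    done1 <- !is.na(l$end_time[i1])
    elig <- which(isTRUE_v(l$asct_planned[i1]) & done1 &
                    !is.na(d$bcr3[i1]) & d$bcr3[i1] != 3)
    if (length(elig)) {
      ce <- line_ctx(p, l, i1[elig], lot = rep(1, length(elig)),
                     bcr_prev = d$bcr3[i1][elig])
      out$asct_receipt <- disc_ds(as.integer(has_asct[elig]), ce,
                                  terms_of("asct_receipt"))
    }
    # maintenance decision is only reached by patients who completed
    # induction alive (a line ending at end of follow-up with no assessed
    # response ended at death or data cutoff)
    mrec <- which(done1 & !(l$end_time[i1] >= censor[i1] - 1e-9 &
                              is.na(l$bcr[i1])))
    if (length(mrec)) {
      pa <- l$patient_id[i1][mrec] %in%
        l$patient_id[l$is_asct & !is.na(l$end_time)]
      cm <- line_ctx(p, l, i1[mrec], lot = rep(1, length(mrec)),
                     post_asct = pa)
      out$maintenance_receipt <- disc_ds(as.integer(l$maintenance[i1][mrec]),
                                         cm, terms_of("maintenance_receipt"))
    }
  }

  # --- regimen multinomial logits ------------------------------------------
  for (lot in 1:2) {
    key <- paste0("regimen_lot", lot)
    cat_ <- if (lot == 1) cfg$lot1_catalog else cfg$lot2_catalog
    ii <- which(chem & !is.na(l$lot) & l$lot == lot)
    if (length(ii)) {
      out[[key]] <- disc_ds(factor(reg_map(l$regimen[ii], cat_),
                                   levels = cat_),
                            line_ctx(p, l, ii, lot = l$lot[ii]),
                            terms_of(key))
    }
  }

  # --- best clinical response ----------------------------------------------
  bcr_idx <- function(sel) which(sel & !is.na(l$bcr) & !is.na(l$end_time))
  add_bcr <- function(key, sel, asct = FALSE) {
    ii <- bcr_idx(sel)
    if (!length(ii)) return()
    lev <- defs[[key]]$levels
    y <- if (length(lev) == 3) {
      factor(collapse_bcr(l$bcr[ii]), levels = 1:3, labels = lev)
    } else factor(l$bcr[ii], levels = lev)
    cat_ <- if (identical(key, "bcr_lot1")) cfg$lot1_catalog
            else if (identical(key, "bcr_lot2")) cfg$lot2_catalog else NULL
    ctxb <- line_ctx(p, l, ii,
                     lot = if (asct) rep(1, length(ii)) else l$lot[ii],
                     bcr_prev = ifelse(is.na(d$prev_bcr3[ii]), 0,
                                       d$prev_bcr3[ii]),
                     post_asct = d$post_asct[ii],
                     regimen = if (is.null(cat_)) NULL else
                       reg_map(l$regimen[ii], cat_))
    out[[key]] <<- disc_ds(y, ctxb, terms_of(key))
  }
  add_bcr("bcr_lot1", chem & !is.na(l$lot) & l$lot == 1)
  add_bcr("bcr_asct", l$is_asct, asct = TRUE)
  for (k in 2:5) add_bcr(paste0("bcr_lot", k),
                         chem & !is.na(l$lot) & l$lot == k)
  add_bcr("bcr_lot6_9", chem & !is.na(l$lot) & l$lot >= 6)

  # --- treatment durations --------------------------------------------------
  add_dur <- function(key, sel, regimen_cat = NULL) {
    ii <- which(sel)
    if (!length(ii)) return()
    tm <- ifelse(!is.na(l$end_time[ii]), l$end_time[ii] - l$start_time[ii],
                 censor[ii] - l$start_time[ii])
    # a line ending at the end of follow-up with no assessed response ended
    # because the patient died (or follow-up closed): censored duration
    ended <- !is.na(l$end_time[ii]) &
      !(l$end_time[ii] >= censor[ii] - 1e-9 & is.na(l$bcr[ii]))
    ok <- tm > 0
    ii <- ii[ok]; tm <- tm[ok]; ended <- ended[ok]
    if (!length(ii)) return()
    ctxd <- line_ctx(p, l, ii,
                     lot = ifelse(is.na(l$lot[ii]), 1, l$lot[ii]),
                     bcr_prev = ifelse(is.na(d$prev_bcr3[ii]), 0,
                                       d$prev_bcr3[ii]),
                     post_asct = d$post_asct[ii],
                     regimen = if (is.null(regimen_cat)) NULL else
                       reg_map(l$regimen[ii], regimen_cat))
    out[[key]] <<- surv_ds(tm, ended, ctxd, terms_of(key))
  }
  planned1 <- chem & !is.na(l$lot) & l$lot == 1 & isTRUE_v(l$asct_planned)
  add_dur("dur_lot1_asct", planned1)
  add_dur("dur_lot1_noasct",
          chem & !is.na(l$lot) & l$lot == 1 & !isTRUE_v(l$asct_planned),
          cfg$lot1_catalog)
  add_dur("dur_lot2", chem & !is.na(l$lot) & l$lot == 2, cfg$lot2_catalog)
  for (k in 3:5) add_dur(paste0("dur_lot", k),
                         chem & !is.na(l$lot) & l$lot == k)
  add_dur("dur_lot6_9", chem & !is.na(l$lot) & l$lot >= 6)
  add_dur("dur_asct", l$is_asct)

  # --- treatment-free intervals / maintenance gap ---------------------------
  comp <- which(chem & !is.na(l$end_time) & !is.na(l$lot) &
                  l$lot < cfg$max_lot)
  if (length(comp)) {
    pid <- l$patient_id[comp]
    # effective end: transplant shifts the LoT-1 gap start to ASCT end
    aend <- l$end_time[l$is_asct]
    apid <- l$patient_id[l$is_asct]
    ongoing_asct <- l$patient_id[l$is_asct & is.na(l$end_time)]
    ma <- match(pid, apid)
    eff_end <- l$end_time[comp]
    gap_bcr <- d$bcr3[comp]
    is1 <- l$lot[comp] == 1
    has_a <- is1 & !is.na(ma)
    eff_end[has_a] <- pmax(eff_end[has_a], aend[ma[has_a]])
    abcr <- collapse_bcr(l$bcr[l$is_asct])
    gap_bcr[has_a] <- ifelse(is.na(abcr[ma[has_a]]), gap_bcr[has_a],
                             abcr[ma[has_a]])
    drop_a <- is1 & pid %in% ongoing_asct
    # next chemotherapy start (l is sorted by patient, start_time)
    lcpos <- which(chem)
    ic <- match(comp, lcpos)
    j2 <- ic + 1
    nxt <- rep(NA_real_, length(comp))
    valid <- j2 <= length(lcpos) &
      l$patient_id[lcpos[pmin(j2, length(lcpos))]] == l$patient_id[comp]
    nxt[valid] <- l$start_time[lcpos[j2[valid]]]
    gtime <- ifelse(!is.na(nxt), nxt - eff_end, censor[comp] - eff_end)
    ok <- !drop_a & !is.na(eff_end) & gtime > 0
    add_gap <- function(key, sel) {
      jj <- which(ok & sel)
      if (!length(jj)) return()
      ctxg <- line_ctx(p, l, comp[jj], lot = l$lot[comp][jj],
                       bcr_prev = ifelse(is.na(gap_bcr[jj]), 0, gap_bcr[jj]),
                       post_asct = has_a[jj])
      out[[key]] <<- surv_ds(gtime[jj], !is.na(nxt[jj]), ctxg, terms_of(key))
    }
    maint <- l$maintenance[comp] %in% TRUE
    add_gap("dur_maintenance", is1 & maint)
    add_gap("tfi_lot1_asct", is1 & !maint & has_a)
    add_gap("tfi_lot1_noasct", is1 & !maint & !has_a)
    for (k in 2:5) add_gap(paste0("tfi_lot", k), l$lot[comp] == k)
    add_gap("tfi_lot6_9", l$lot[comp] >= 6)
  }
  out
}

isTRUE_v <- function(x) !is.na(x) & x

fit_dataset <- function(def, ds, knots = NULL) {
  if (ds$kind == "surv") {
    fit_parametric_survival(ds$time, ds$event, ds$X, def$family,
                            tstart = ds$tstart, knots = knots,
                            outcome = def$outcome, state = def$state)
  } else {
    fit_discrete(ds$y, ds$X, def$family, outcome = def$outcome,
                 state = def$state)
  }
}

# drop constant (non-identifiable) columns so small-state fits stay stable
prune_dataset <- function(ds) {
  if (!ncol(ds$X)) return(ds)
  keep <- apply(ds$X, 2, function(c) stats::var(c) > 0)
  ds$X <- ds$X[, keep, drop = FALSE]
  ds
}

#' Estimate the full risk-equation set from multiply imputed registries
#'
#' For every equation in the framework configuration, builds the estimation
#' dataset from each completed registry, fits the equation per imputation,
#' and pools coefficients across imputations by Rubin's rules. Constant
#' covariate columns within a state are dropped from that state's equation
#' (their coefficients are not identifiable there). Duration and
#' treatment-free-interval curtailment maxima (the largest observed event
#' time per state) are recorded alongside the coefficients. If a state's
#' fit fails with the full covariate set, it falls back to an
#' intercept-only fit for that state with a warning.
#'
#' @param imputed_tables list of m completed `registry_table`s (see
#'   [impute_registry()])
#' @param cfg a `framework_config`; defaults to catalogs derived from the
#'   first table under the 10% regimen rule
#' @return a `model_coefficients` set; each equation carries its pooled
#'   Rubin's-rules table in `$pooled`
#' @export
estimate_all_equations <- function(imputed_tables, cfg = NULL) {
  stopifnot(length(imputed_tables) >= 1)
  tables <- lapply(imputed_tables, drop_unended_lines)
  if (is.null(cfg)) {
    cfg <- framework_config(
      lot1_catalog = regimen_catalog(tables[[1]], 1),
      lot2_catalog = regimen_catalog(tables[[1]], 2))
  }
  data_list <- lapply(tables, build_estimation_data, cfg = cfg)
  defs <- cfg$equations
  missing_keys <- setdiff(names(defs), names(data_list[[1]]))
  if (length(missing_keys))
    stop_("no observations to estimate equation(s): %s",
          paste(missing_keys, collapse = ", "))
  m <- length(tables)
  eqs <- list()
  for (key in names(defs)) {
    def <- defs[[key]]
    knots <- NULL
    if (def$family == "weibull_spline3") {
      ds1 <- data_list[[1]][[key]]
      ze <- log(pmax(ds1$time[ds1$event == 1], 1e-6))
      knots <- unname(c(min(ze), stats::quantile(ze, c(.25, .5, .75)),
                        max(ze)))
    }
    fits <- lapply(seq_len(m), function(j) {
      ds <- prune_dataset(data_list[[j]][[key]])
      tryCatch(fit_dataset(def, ds, knots = knots), error = function(e) {
        warning(sprintf(
          "equation '%s', imputation %d: %s; refitting intercept-only",
          key, j, conditionMessage(e)), call. = FALSE)
        ds0 <- ds; ds0$X <- ds0$X[, 0, drop = FALSE]
        fit_dataset(def, ds0, knots = knots)
      })
    })
    layouts <- vapply(fits, function(f) paste(names(f$par), collapse = "|"),
                      character(1))
    use <- layouts == names(sort(table(layouts), decreasing = TRUE))[1]
    if (!all(use))
      warning(sprintf("equation '%s': %d of %d imputations had a different
parameter layout and were excluded from pooling", key, sum(!use), m),
              call. = FALSE)
    fsub <- fits[use]
    pooled <- pool_rubin(lapply(fsub, function(f) f$par),
                         lapply(fsub, function(f) {
                           v <- diag(f$vcov)
                           v[!is.finite(v)] <- 0
                           stats::setNames(v, names(f$par))
                         }))
    eq <- rebuild_equation(fsub[[1]], stats::setNames(pooled$estimate,
                                                      pooled$term))
    eq$pooled <- pooled
    eqs[[key]] <- eq
  }
  curt <- c()
  for (key in names(defs)) {
    if (defs[[key]]$family %in% surv_families() && key != "os") {
      ds <- data_list[[1]][[key]]
      mx <- suppressWarnings(max(ds$time[ds$event == 1]))
      curt[key] <- if (is.finite(mx)) mx else Inf
    }
  }
  model_coefficients(eqs, curt, cfg)
}

# rebuild a risk_equation from a pooled estimation-scale parameter vector,
# using a fitted equation as the layout template
rebuild_equation <- function(template, par) {
  eq <- template
  eq$par <- par
  tn <- template$term_names
  k <- length(tn)
  if (template$family %in% c("gompertz", "weibull")) {
    eq$beta <- par[seq_len(k + 1)]
    eq$ancillary$shape <- if (template$family == "gompertz")
      unname(par[k + 2]) else exp(unname(par[k + 2]))
  } else if (template$family == "weibull_spline3") {
    ng <- length(template$ancillary$gamma)
    eq$ancillary$gamma <- unname(par[seq_len(ng)])
    eq$beta <- par[-seq_len(ng)]
  } else if (template$family == "logit") {
    eq$beta <- par
  } else if (template$family == "ologit") {
    eq$beta <- par[seq_len(k)]
    eq$ancillary$cutpoints <- unname(if (k) par[-seq_len(k)] else par)
  } else if (template$family == "mlogit") {
    eq$beta <- par
    cf <- template$ancillary$coef
    eq$ancillary$coef <- matrix(par, nrow = nrow(cf), byrow = TRUE,
                                dimnames = dimnames(cf))
  }
  eq
}
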