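# Multiple imputation by chained equations for the registry's missing
# ECOG, ISS and best-clinical-response values, plus Rubin's-rules pooling.
#
# ECOG and ISS are imputed at the patient level by ordinal logistic models
# on age, sex, the log laboratory markers and each other, cycling for a few
# sweeps; response is imputed at the line level, on the 6-level scale, from
# the within-line laboratory changes and line number — whose predictors are
# fully observed, so that model needs no sweeps. Imputation is "proper": each
# conditional model's coefficients are drawn from their approximate posterior
# (normal around the MLE) before drawing the missing categories from the
# posterior-predictive category probabilities. Observed values are never
# altered.

#' Imputation specification
#'
#' @param m number of completed datasets (default 10)
#' @param max_iter chained-equation sweeps over the patient-level variables
#'   (default 5)
#' @param seed integer seed; imputations are reproducible and independent
#' @param variable_models named list mapping each imputed variable to
#'   `list(predictors = ...)`; defaults impute ECOG and ISS from age, sex,
#'   log labs and each other, and response from the within-line laboratory
#'   changes and line number
#' @return object of class `imputation_spec`
#' @export
imputation_spec <- function(m = 10, max_iter = 5, seed = 1,
                            variable_models = NULL) {
  stopifnot(m >= 2, max_iter >= 1)
  vm <- variable_models %||% list(
    ecog = list(predictors = c("age_dec", "male", "log_pp", "log_kappa",
                               "log_lambda", "iss2", "iss3")),
    iss = list(predictors = c("age_dec", "male", "log_pp", "log_kappa",
                              "log_lambda", "ecog1", "ecog2plus")),
    bcr = list(predictors = c("dpp", "dkappa", "dlambda", "lot_c")))
  for (v in names(vm)) {
    if (v %in% vm[[v]]$predictors)
      stop_("imputation model for '%s' may not predict from itself", v)
  }
  structure(list(m = m, max_iter = max_iter, seed = seed,
                 variable_models = vm), class = "imputation_spec")
}

# draw coefficients from the approximate posterior of a polr fit, then draw
# categories for the missing rows from the implied probabilities
draw_ordinal <- function(yobs, Xobs, Xmis) {
  df <- as.data.frame(Xobs)
  df$.y <- droplevels(yobs)
  fit <- MASS::polr(stats::reformulate(colnames(Xobs), ".y"), data = df,
                    Hess = TRUE)
  par <- c(stats::coef(fit), fit$zeta)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (!is.null(vc) && all(is.finite(vc))) {
    par <- MASS::mvrnorm(1, par, vc)
  }
  k <- ncol(Xobs)
  beta <- par[seq_len(k)]
  zeta <- sort(par[-seq_len(k)])
  eta <- drop(as.matrix(Xmis) %*% beta)
  cum <- stats::plogis(outer(eta, zeta, function(e, z) z - e))
  cum <- cbind(cum, 1)
  u <- stats::runif(nrow(cum))
  idx <- rowSums(cum < u) + 1
  lev <- levels(droplevels(yobs))
  lev[pmin(idx, length(lev))]
}

pat_predictors <- function(p) {
  fill <- function(v) ifelse(is.na(v), stats::median(v, na.rm = TRUE), v)
  data.frame(age_dec = (p$age_dx - 65) / 10,
             male = as.numeric(p$sex == "male"),
             log_pp = log(fill(pmax(p$paraprotein, 1e-3))),
             log_kappa = log(fill(pmax(p$kappa_lc, 1e-3))),
             log_lambda = log(fill(pmax(p$lambda_lc, 1e-3))))
}

#' Multiple imputation of a registry by chained equations
#'
#' Returns `m` completed copies of the registry with ECOG, ISS and
#' best-clinical-response filled in (response only on assessed —
#' completed — treatment rows is used downstream; all missing response
#' values are nevertheless imputed). With no missing data the result is `m`
#' identical copies of the input.
#'
#' @param table a `registry_table`
#' @param spec an [imputation_spec()]
#' @return list of `m` completed `registry_table`s
#' @export
impute_registry <- function(table, spec = imputation_spec()) {
  p <- table$patients
  l <- table$lines
  mis_ecog <- is.na(p$ecog)
  mis_iss <- is.na(p$iss)
  mis_bcr <- is.na(l$bcr)
  vm <- spec$variable_models
  if (!any(mis_ecog) && !any(mis_iss) && !any(mis_bcr)) {
    return(replicate(spec$m, table, simplify = FALSE))
  }
  for (v in c("dpp", "dkappa", "dlambda")) {
    if (any(mis_bcr) && all(is.na(l[[v]])))
      stop_("imputation predictor '%s' is entirely missing", v)
  }
  base_pred <- pat_predictors(p)
  lapply(seq_len(spec$m), function(j) {
    with_seed(derive_seed(spec$seed, 7, j), {
      ecog <- p$ecog
      iss <- p$iss
      # initialize missing entries from the observed marginals
      if (any(mis_ecog))
        ecog[mis_ecog] <- sample(ecog[!mis_ecog], sum(mis_ecog), TRUE)
      if (any(mis_iss))
        iss[mis_iss] <- sample(iss[!mis_iss], sum(mis_iss), TRUE)
      for (sweep in seq_len(spec$max_iter)) {
        if (any(mis_ecog)) {
          X <- cbind(base_pred, iss2 = as.numeric(iss == 2),
                     iss3 = as.numeric(iss == 3))
          X <- X[, vm$ecog$predictors, drop = FALSE]
          ecog[mis_ecog] <- draw_ordinal(
            factor(p$ecog[!mis_ecog], levels = c("0", "1", "2plus")),
            X[!mis_ecog, , drop = FALSE], X[mis_ecog, , drop = FALSE])
        }
        if (any(mis_iss)) {
          X <- cbind(base_pred, ecog1 = as.numeric(ecog == "1"),
                     ecog2plus = as.numeric(ecog == "2plus"))
          X <- X[, vm$iss$predictors, drop = FALSE]
          iss[mis_iss] <- as.integer(draw_ordinal(
            factor(p$iss[!mis_iss], levels = 1:3),
            X[!mis_iss, , drop = FALSE], X[mis_iss, , drop = FALSE]))
        }
        if (!any(mis_ecog) || !any(mis_iss)) break  # nothing to cycle
      }
      bcr <- l$bcr
      if (any(mis_bcr)) {
        Xl <- data.frame(dpp = l$dpp, dkappa = l$dkappa, dlambda = l$dlambda,
                         lot_c = pmax(ifelse(is.na(l$lot), 1, l$lot) - 1, 0))
        for (v in names(Xl)) {
          Xl[[v]][is.na(Xl[[v]])] <- stats::median(Xl[[v]], na.rm = TRUE)
        }
        Xl <- Xl[, vm$bcr$predictors, drop = FALSE]
        bcr[mis_bcr] <- draw_ordinal(
          factor(l$bcr[!mis_bcr], levels = bcr_levels()),
          Xl[!mis_bcr, , drop = FALSE], Xl[mis_bcr, , drop = FALSE])
      }
      p2 <- p; p2$ecog <- ecog; p2$iss <- iss
      l2 <- l; l2$bcr <- bcr
      registry_table(p2, l2)
    })
  })
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate Q-bar = mean of the per-imputation estimates; within
#' variance W = mean of the per-imputation variances; between variance B =
#' sample variance of the estimates; total variance T = W + (1 + 1/m) B;
#' degrees of freedom by the standard small-sample formula
#' (m - 1) (1 + W / ((1 + 1/m) B))^2.
#'
#' @param estimates list of m named coefficient vectors with identical layout
#' @param variances list of m matching squared-standard-error vectors
#' @return data frame with columns `term`, `estimate`, `within_var`,
#'   `between_var`, `total_var`, `dof`
#' @export
pool_rubin <- function(estimates, variances) {
  m <- length(estimates)
  stopifnot(m >= 1, length(variances) == m)
  lay <- vapply(estimates, function(e) paste(names(e), collapse = "|"),
                character(1))
  if (length(unique(lay)) != 1)
    stop_("cannot pool: imputation fits have mismatched parameter layouts")
  Q <- do.call(rbind, estimates)
  V <- do.call(rbind, variances)
  qbar <- colMeans(Q)
  W <- colMeans(V)
  B <- if (m > 1) apply(Q, 2, stats::var) else rep(0, ncol(Q))
  Tt <- W + (1 + 1 / m) * B
  dof <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  data.frame(term = colnames(Q) %||% paste0("par", seq_along(qbar)),
             estimate = unname(qbar), within_var = unname(W),
             between_var = unname(B), total_var = unname(Tt),
             dof = unname(dof), stringsAsFactors = FALSE)
}
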