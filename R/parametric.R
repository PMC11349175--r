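# Parametric proportional-hazards machinery.
#
# All time-to-event risk equations share the PH form  h(t | x) = h0(t) exp(x'b)
# with three baseline families:
#   gompertz        h0(t) = lambda exp(gamma t),      lambda = exp(b0)
#   weibull         h0(t) = lambda p t^(p-1)
#   weibull_spline3 log H(t | x) = s(log t; gamma) + x'b, s a natural cubic
#                   spline with 3 interior knots (flexible parametric model)
# Cumulative hazards have closed forms (spline: closed form in log t), which
# is what makes exact conditional inverse-transform sampling possible in the
# simulation engine.

surv_families <- function() c("gompertz", "weibull", "weibull_spline3")

# ---- restricted cubic spline basis on log time --------------------------

rcs_basis <- function(z, knots) {
  kmin <- knots[1]; kmax <- knots[length(knots)]
  interior <- knots[-c(1, length(knots))]
  out <- cbind(1, z)
  for (kj in interior) {
    lam <- (kmax - kj) / (kmax - kmin)
    out <- cbind(out, pmax(z - kj, 0)^3 - lam * pmax(z - kmin, 0)^3 -
                   (1 - lam) * pmax(z - kmax, 0)^3)
  }
  out
}

rcs_dbasis <- function(z, knots) {
  kmin <- knots[1]; kmax <- knots[length(knots)]
  interior <- knots[-c(1, length(knots))]
  out <- cbind(rep(0, length(z)), rep(1, length(z)))
  for (kj in interior) {
    lam <- (kmax - kj) / (kmax - kmin)
    out <- cbind(out, 3 * pmax(z - kj, 0)^2 - 3 * lam * pmax(z - kmin, 0)^2 -
                   3 * (1 - lam) * pmax(z - kmax, 0)^2)
  }
  out
}

# ---- cumulative hazard / hazard -----------------------------------------

# stable (exp(g t) - 1)/g and its derivative in g
gomp_g <- function(t, g) {
  if (abs(g) < 1e-9) t * (1 + g * t / 2) else expm1(g * t) / g
}
gomp_dg <- function(t, g) {
  if (abs(g) < 1e-9) t^2 / 2 + g * t^3 / 3
  else (t * exp(g * t) * g - expm1(g * t)) / g^2
}

# eta: linear predictor x'b (including intercept for gompertz/weibull;
# excluding it for the spline, whose intercept lives in gamma0)
cumhaz_param <- function(t, family, eta, ancillary) {
  H <- numeric(length(t))
  pos <- t > 0
  if (!any(pos)) return(H)
  tp <- t[pos]
  ep <- if (length(eta) == 1) eta else eta[pos]
  H[pos] <- switch(family,
    gompertz = exp(ep) * gomp_g(tp, ancillary$shape),
    weibull = exp(ep) * tp^ancillary$shape,
    weibull_spline3 = {
      z <- log(tp)
      exp(drop(rcs_basis(z, ancillary$knots) %*% ancillary$gamma) + ep)
    },
    stop_("unknown survival family '%s'", family))
  H
}

loghaz_param <- function(t, family, eta, ancillary) {
  switch(family,
    gompertz = eta + ancillary$shape * t,
    weibull = eta + log(ancillary$shape) +
      (ancillary$shape - 1) * log(t),
    weibull_spline3 = {
      z <- log(t)
      B <- rcs_basis(z, ancillary$knots)
      dB <- rcs_dbasis(z, ancillary$knots)
      sp <- drop(dB %*% ancillary$gamma)
      # hazard h = H * s'(z) / t; invalid (non-monotone) spline regions get -Inf
      ifelse(sp > 0,
             drop(B %*% ancillary$gamma) + eta + log(pmax(sp, 1e-300)) - z,
             -Inf)
    },
    stop_("unknown survival family '%s'", family))
}

eq_eta <- function(eq, x) {
  tn <- eq$term_names
  if (!length(tn)) return(if (eq$family %in% c("gompertz", "weibull", "logit"))
    unname(eq$beta[["(Intercept)"]]) else 0)
  if (is.null(names(x))) stop_("covariate vector must be named")
  miss <- setdiff(tn, names(x))
  if (length(miss)) stop_("missing covariate(s): %s", paste(miss, collapse = ", "))
  eta <- sum(eq$beta[tn] * x[tn])
  if ("(Intercept)" %in% names(eq$beta)) eta <- eta + eq$beta[["(Intercept)"]]
  unname(eta)
}

#' Survival function of a fitted time-to-event risk equation
#'
#' Evaluates S(t | x) = exp(-H(t | x)) under the equation's
#' proportional-hazards parameterization: Gompertz
#' S(t) = exp(-(lambda/gamma)(e^(gamma t) - 1)), Weibull S(t) = exp(-lambda t^p)
#' with lambda = exp(x'b), and the spline family from its log-cumulative-hazard
#' representation. S(0) = 1 in every family.
#'
#' @param t vector of non-negative times (months)
#' @param eq a survival `risk_equation`
#' @param x named covariate vector (may be empty for intercept-only equations)
#' @return vector of survival probabilities in \[0, 1\]
#' @export
survival_value <- function(t, eq, x = numeric(0)) {
  if (any(t < 0)) stop_("t must be non-negative")
  eta <- eq_eta(eq, x)
  exp(-cumhaz_param(t, eq$family, eta, eq$ancillary))
}

#' Conditional inverse-transform event-time sampling
#'
#' Solves S(t) = u * S(t0) for t > t0 — i.e. maps a uniform draw on
#' (0, S(t0)) through the inverse conditional survival function, the scheme
#' the simulation engine uses to predict death (and state durations with
#' t0 = 0) from each health-state entry. Gompertz and Weibull invert in
#' closed form; the spline family is inverted numerically on the log-time
#' scale. A Gompertz equation with negative shape has a surviving fraction
#' S(Inf) = exp(lambda/gamma); draws landing below it return `Inf` (the event
#' never happens; the caller curtails).
#'
#' @param eq survival `risk_equation`
#' @param x named covariate vector
#' @param t0 current time (months, >= 0)
#' @param u uniform draw strictly inside (0, 1)
#' @return event time > t0, or `Inf`
#' @export
conditional_event_time <- function(eq, x = numeric(0), t0 = 0, u) {
  if (t0 < 0) stop_("t0 must be non-negative")
  if (!is.finite(u) || u <= 0 || u >= 1) stop_("u must lie strictly in (0, 1)")
  eta <- eq_eta(eq, x)
  anc <- eq$ancillary
  Htar <- cumhaz_param(t0, eq$family, eta, anc) - log(u)
  lam <- exp(eta)
  switch(eq$family,
    gompertz = {
      g <- anc$shape
      if (abs(g) < 1e-9) {
        Htar / lam * (1 - g * Htar / (2 * lam))
      } else {
        arg <- 1 + g * Htar / lam
        if (arg <= 0) Inf else log(arg) / g
      }
    },
    weibull = (Htar / lam)^(1 / anc$shape),
    weibull_spline3 = {
      target <- log(Htar) - eta
      f <- function(z) drop(rcs_basis(z, anc$knots) %*% anc$gamma) - target
      lo <- anc$knots[1] - 20; hi <- anc$knots[length(anc$knots)] + 20
      while (f(lo) > 0 && lo > -200) lo <- lo - 20
      while (f(hi) < 0 && hi < 200) hi <- hi + 20
      if (f(hi) < 0) return(Inf)
      exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
    },
    stop_("unknown survival family '%s'", eq$family))
}

# ---- maximum-likelihood fitting -----------------------------------------

negll_surv <- function(par, family, time, event, tstart, X, knots) {
  k <- ncol(X)
  if (family == "weibull_spline3") {
    gam <- par[seq_len(length(knots))]
    beta <- if (k) par[-seq_len(length(knots))] else numeric(0)
    eta <- if (k) drop(X %*% beta) else rep(0, length(time))
    anc <- list(knots = knots, gamma = gam)
  } else {
    beta <- par[seq_len(k + 1)]
    eta <- drop(cbind(1, X) %*% beta)
    anc <- if (family == "gompertz") list(shape = par[k + 2])
           else list(shape = exp(par[k + 2]))
  }
  H1 <- cumhaz_param(time, family, eta, anc)
  H0 <- if (is.null(tstart)) 0 else cumhaz_param(tstart, family, eta, anc)
  lh <- loghaz_param(time[event == 1], family,
                     if (length(eta) > 1) eta[event == 1] else eta, anc)
  if (any(!is.finite(lh))) return(1e10)
  ll <- sum(lh) - sum(H1 - H0)
  if (!is.finite(ll)) return(1e10)
  -ll
}

grad_negll_surv <- function(par, family, time, event, tstart, X, knots) {
  k <- ncol(X)
  Xi <- cbind(1, X)
  beta <- par[seq_len(k + 1)]
  eta <- drop(Xi %*% beta)
  lam <- exp(eta)
  t0 <- if (is.null(tstart)) rep(0, length(time)) else tstart
  if (family == "gompertz") {
    g <- par[k + 2]
    dg <- gomp_g(time, g) - gomp_g(t0, g)
    dH_dg <- lam * (gomp_dg(time, g) - gomp_dg(t0, g))
    gb <- drop(crossprod(Xi, event - lam * dg))
    gs <- sum(event * time) - sum(dH_dg)
  } else {
    p <- exp(par[k + 2])
    tp <- time^p; t0p <- ifelse(t0 > 0, t0^p, 0)
    gb <- drop(crossprod(Xi, event - lam * (tp - t0p)))
    dlogt <- ifelse(t0 > 0, t0p * log(t0), 0)
    dll_dp <- sum(event * (1 / p + log(time))) -
      sum(lam * (tp * log(time) - dlogt))
    gs <- p * dll_dp
  }
  -c(gb, gs)
}

grad_negll_spline <- function(par, family, time, event, tstart, X, knots) {
  G <- length(knots)
  k <- ncol(X)
  gam <- par[seq_len(G)]
  beta <- if (k) par[-seq_len(G)] else numeric(0)
  eta <- if (k) drop(X %*% beta) else rep(0, length(time))
  z1 <- log(time)
  B1 <- rcs_basis(z1, knots)
  H1 <- exp(drop(B1 %*% gam) + eta)
  if (!is.null(tstart)) {
    pos <- tstart > 0
    H0 <- numeric(length(time))
    B0w <- matrix(0, length(time), G)
    if (any(pos)) {
      z0 <- log(tstart[pos])
      B0 <- rcs_basis(z0, knots)
      H0[pos] <- exp(drop(B0 %*% gam) + eta[pos])
      B0w[pos, ] <- B0 * H0[pos]
    }
  } else {
    H0 <- 0
    B0w <- 0
  }
  e <- event == 1
  dBe <- rcs_dbasis(z1[e], knots)
  spe <- drop(dBe %*% gam)
  if (any(spe <= 0)) return(rep(0, length(par)))  # penalty region
  g_gam <- colSums(B1[e, , drop = FALSE]) + colSums(dBe / spe) -
    colSums(B1 * H1 - B0w)
  g_beta <- if (k) drop(crossprod(X, event - (H1 - H0))) else numeric(0)
  -c(g_gam, g_beta)
}

#' Fit a parametric proportional-hazards survival risk equation
#'
#' Maximum-likelihood fit of the Gompertz, Weibull, or 3-interior-knot
#' flexible spline family with rate lambda = exp(x'b). Supports right
#' censoring and left truncation (`tstart`, used by the overall-survival
#' equation, which is estimated on health-state entry episodes).
#'
#' @param time event/censoring times (> 0; months)
#' @param event 1 = event, 0 = censored (at least one event required)
#' @param X covariate matrix without intercept column (or `NULL`)
#' @param family one of `"gompertz"`, `"weibull"`, `"weibull_spline3"`
#' @param tstart optional left-truncation entry times (default 0)
#' @param knots spline boundary+interior knots on log time; default boundary
#'   at the range and interior at the 25/50/75 percentiles of observed log
#'   event times
#' @param outcome,state labels stored on the returned equation key
#' @return a `risk_equation` with coefficients, ancillary shape parameters,
#'   variance matrix and fit statistics (log-likelihood, AIC, BIC)
#' @export
fit_parametric_survival <- function(time, event, X = NULL,
                                    family = c("gompertz", "weibull",
                                               "weibull_spline3"),
                                    tstart = NULL, knots = NULL,
                                    outcome = "", state = "") {
  family <- match.arg(family)
  event <- as.integer(event)
  if (sum(event) < 1) stop_("cannot fit '%s': no events observed", family)
  if (any(time <= 0)) time <- pmax(time, 1e-6)
  if (is.null(X)) X <- matrix(numeric(0), nrow = length(time), ncol = 0)
  X <- as.matrix(X)
  term_names <- colnames(X) %||% character(0)
  k <- ncol(X)
  rate0 <- log(sum(event) / sum(time - (tstart %||% 0)))
  if (family == "weibull_spline3") {
    if (is.null(knots)) {
      ze <- log(time[event == 1])
      knots <- unname(c(min(ze), stats::quantile(ze, c(.25, .5, .75)), max(ze)))
      if (any(duplicated(round(knots, 8))))
        knots <- unname(seq(min(ze), max(ze), length.out = 5))
    }
    # start from the nested Weibull solution (gamma2..4 = 0) so the spline
    # fit can only improve on it
    wfit <- fit_parametric_survival(time, event, X, "weibull",
                                    tstart = tstart)
    par0 <- c(wfit$beta[["(Intercept)"]],        # gamma0 = log lambda
              wfit$ancillary$shape,              # gamma1 = p
              rep(0, length(knots) - 2),
              if (k) unname(wfit$beta[term_names]) else numeric(0))
    pnames <- c(paste0("gamma", seq_along(knots) - 1), term_names)
    gr <- grad_negll_spline
  } else {
    par0 <- c(rate0, rep(0, k), 0)
    pnames <- c("(Intercept)", term_names,
                if (family == "gompertz") "shape" else "log_shape")
    gr <- grad_negll_surv
  }
  fit <- stats::optim(par0, negll_surv, gr = gr, family = family, time = time,
                      event = event, tstart = tstart, X = X, knots = knots,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-9))
  if (fit$convergence != 0)
    stop_("ML fit of '%s' failed to converge (code %d, %d evaluations): %s",
          family, fit$convergence, fit$counts[1], fit$message %||% "")
  par <- stats::setNames(fit$par, pnames)
  vc <- tryCatch(solve(fit$hessian), error = function(e) {
    matrix(NA_real_, length(par), length(par))
  })
  dimnames(vc) <- list(pnames, pnames)
  if (family == "weibull_spline3") {
    beta <- par[-seq_along(knots)]
    anc <- list(knots = knots, gamma = unname(par[seq_along(knots)]))
  } else {
    beta <- par[seq_len(k + 1)]
    anc <- if (family == "gompertz") list(shape = unname(par[k + 2]))
           else list(shape = exp(unname(par[k + 2])))
  }
  ll <- -fit$value
  npar <- length(par)
  new_risk_equation(
    outcome = outcome, state = state, family = family, beta = beta,
    term_names = term_names, ancillary = anc, par = par, vcov = vc,
    stats = list(loglik = ll, aic = -2 * ll + 2 * npar,
                 bic = -2 * ll + log(length(time)) * npar,
                 n = length(time), nevents = sum(event),
                 fingerprint = c(length(time), sum(event),
                                 round(sum(time), 6))))
}

new_risk_equation <- function(outcome, state, family, beta, term_names,
                              ancillary, par = NULL, vcov = NULL,
                              stats = NULL) {
  structure(list(outcome = outcome, state = state, family = family,
                 beta = beta, term_names = term_names, ancillary = ancillary,
                 par = par, vcov = vcov, stats = stats),
            class = "risk_equation")
}

#' @export
print.risk_equation <- function(x, ...) {
  cat(sprintf("<risk_equation> %s%s [%s], %d term(s)\n", x$outcome,
              if (nzchar(x$state)) paste0("/", x$state) else "",
              x$family, length(x$term_names)))
  if (!is.null(x$stats))
    cat(sprintf("  n = %s, loglik = %.2f, AIC = %.2f\n", x$stats$n,
                x$stats$loglik, x$stats$aic))
  invisible(x)
}

#' Select among candidate survival distributions by information criterion
#'
#' Compares candidate fits of the same data and returns the minimum-AIC
#' equation (ties broken by the fixed family order gompertz, weibull,
#' weibull_spline3). A comparison table of AIC/BIC/log-likelihood is attached
#' as attribute `"comparison"` for goodness-of-fit inspection.
#'
#' @param fits list of survival `risk_equation`s fitted to identical data
#' @return the selected `risk_equation`
#' @export
select_distribution <- function(fits) {
  if (!length(fits)) stop_("no candidate fits supplied")
  if (length(fits) == 1) return(fits[[1]])
  fps <- lapply(fits, function(f) f$stats$fingerprint)
  if (!all(vapply(fps, identical, logical(1), y = fps[[1]])))
    stop_("candidate fits were estimated on different data")
  tab <- data.frame(
    family = vapply(fits, `[[`, character(1), "family"),
    loglik = vapply(fits, function(f) f$stats$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$stats$aic, numeric(1)),
    bic = vapply(fits, function(f) f$stats$bic, numeric(1)))
  ord <- order(round(tab$aic, 8), match(tab$family, surv_families()))
  best <- fits[[ord[1]]]
  attr(best, "comparison") <- tab
  best
}
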