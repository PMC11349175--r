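# Discrete-outcome risk equations: binary logit (planned ASCT, ASCT receipt,
# maintenance receipt), multinomial logit (chemotherapy regimen), ordered
# logit (best clinical response). Fitting is delegated to glm / nnet::multinom
# / MASS::polr; this file normalizes their output into the package's
# risk_equation container and provides the probability evaluators the
# simulation engine draws from.

#' Fit a logit / multinomial-logit / ordered-logit risk equation
#'
#' The ordered logit uses the cumulative form
#' P(Y <= k | x) = logistic(tau_k - x'b) with category 1 the best response
#' (Complete Response first for BCR equations). The multinomial logit fixes
#' the most frequent category as the zero-coefficient reference unless
#' `reference` is given.
#'
#' @param y outcome: 0/1 vector (logit), factor (mlogit), or ordered-capable
#'   factor with levels best to worst (ologit)
#' @param X covariate matrix without intercept (or `NULL`)
#' @param family `"logit"`, `"mlogit"` or `"ologit"`
#' @param reference reference category label (mlogit only)
#' @param outcome,state labels stored on the equation key
#' @return a `risk_equation`
#' @export
fit_discrete <- function(y, X = NULL, family = c("logit", "mlogit", "ologit"),
                         reference = NULL, outcome = "", state = "") {
  family <- match.arg(family)
  if (is.null(X)) X <- matrix(numeric(0), nrow = length(y), ncol = 0)
  X <- as.matrix(X)
  term_names <- colnames(X) %||% character(0)
  df <- as.data.frame(X)
  # formula-safe synthetic column names (terms like "regimen:VRd" would
  # parse as interactions); coefficient names are mapped back afterwards
  safe <- if (length(term_names)) paste0(".v", seq_along(term_names))
          else character(0)
  names(df) <- safe
  unsafe_rename <- function(nm) {
    i <- match(nm, safe)
    ifelse(is.na(i), nm, term_names[i])
  }
  form <- stats::reformulate(if (length(safe)) safe else "1",
                             response = ".y")
  sep_err <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        stop_(paste("perfect separation detected while fitting '%s';",
                    "remove or penalize the offending covariate"), family)
      invokeRestart("muffleWarning")
    })
  }
  if (family == "logit") {
    df$.y <- as.integer(y)
    if (length(unique(df$.y)) < 2)
      stop_("logit outcome has a single observed category")
    fit <- sep_err(stats::glm(form, data = df, family = stats::binomial()))
    par <- stats::coef(fit)
    names(par) <- unsafe_rename(names(par))
    vc <- stats::vcov(fit)
    dimnames(vc) <- list(names(par), names(par))
    eq <- new_risk_equation(outcome, state, "logit", beta = par,
                            term_names = term_names, ancillary = list(),
                            par = par, vcov = vc,
                            stats = fit_stats(stats::logLik(fit), length(par),
                                              nrow(df)))
  } else if (family == "ologit") {
    yf <- droplevels(if (is.factor(y)) y else factor(y))
    if (nlevels(yf) < 2)
      stop_("ordered-logit outcome has a single observed category")
    df$.y <- yf
    fit <- MASS::polr(form, data = df, Hess = TRUE)
    beta <- if (length(term_names)) stats::coef(fit) else
      stats::setNames(numeric(0), character(0))
    names(beta) <- unsafe_rename(names(beta))
    zeta <- fit$zeta
    names(zeta) <- paste0("tau", seq_along(zeta))
    par <- c(beta, zeta)
    vc <- stats::vcov(fit)
    dimnames(vc) <- list(names(par), names(par))
    eq <- new_risk_equation(outcome, state, "ologit", beta = beta,
                            term_names = term_names,
                            ancillary = list(cutpoints = unname(zeta),
                                             levels = levels(yf)),
                            par = par, vcov = vc,
                            stats = fit_stats(stats::logLik(fit), length(par),
                                              nrow(df)))
  } else {
    yf <- droplevels(factor(y))
    if (nlevels(yf) < 2) stop_("mlogit outcome has a single observed category")
    ref <- reference %||% names(which.max(table(yf)))
    yf <- stats::relevel(yf, ref = ref)
    df$.y <- yf
    fit <- nnet::multinom(form, data = df, trace = FALSE, Hess = TRUE,
                          maxit = 500)
    cf <- stats::coef(fit)
    if (is.null(dim(cf))) {  # two categories: coerce to matrix
      cf <- matrix(cf, nrow = 1,
                   dimnames = list(levels(yf)[2], names(cf)))
    }
    safe_names <- paste(rep(rownames(cf), each = ncol(cf)),
                        rep(colnames(cf), nrow(cf)), sep = ":")
    colnames(cf) <- unsafe_rename(colnames(cf))
    par <- stats::setNames(as.vector(t(cf)),
                           paste(rep(rownames(cf), each = ncol(cf)),
                                 rep(colnames(cf), nrow(cf)), sep = ":"))
    vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
    if (!is.null(vc)) {
      vc <- vc[safe_names, safe_names, drop = FALSE]
      dimnames(vc) <- list(names(par), names(par))
    }
    eq <- new_risk_equation(outcome, state, "mlogit", beta = par,
                            term_names = term_names,
                            ancillary = list(levels = levels(yf),
                                             coef = cf),
                            par = par, vcov = vc,
                            stats = fit_stats(stats::logLik(fit), length(par),
                                              nrow(df)))
  }
  eq
}

fit_stats <- function(ll, npar, n) {
  ll <- as.numeric(ll)
  list(loglik = ll, aic = -2 * ll + 2 * npar,
       bic = -2 * ll + log(n) * npar, n = n, nevents = NA_integer_,
       fingerprint = c(n, NA, NA))
}

#' Category probabilities of a discrete risk equation
#'
#' @param eq a `logit`, `mlogit` or `ologit` `risk_equation`
#' @param x named covariate vector
#' @return named probability vector over the equation's categories (for
#'   `logit`, the single event probability)
#' @export
category_probs <- function(eq, x = numeric(0)) {
  if (eq$family == "logit") {
    return(stats::plogis(eq_eta(eq, x)))
  }
  if (eq$family == "ologit") {
    eta <- if (length(eq$term_names)) sum(eq$beta[eq$term_names] * x[eq$term_names]) else 0
    cum <- stats::plogis(eq$ancillary$cutpoints - eta)
    p <- diff(c(0, cum, 1))
    return(stats::setNames(p, eq$ancillary$levels))
  }
  if (eq$family == "mlogit") {
    cf <- eq$ancillary$coef
    xi <- c(1, if (length(eq$term_names)) x[eq$term_names] else numeric(0))
    etas <- c(0, drop(cf %*% xi))
    p <- exp(etas - max(etas))
    p <- p / sum(p)
    return(stats::setNames(p, eq$ancillary$levels))
  }
  stop_("'%s' is not a discrete risk equation family", eq$family)
}

#' Bernoulli decision from a probability and a uniform draw
#'
#' The event occurs iff `r < p`, so the long-run event rate equals `p`.
#'
#' @param p event probability in \[0, 1\]
#' @param r uniform draw in \[0, 1\]
#' @return logical
#' @export
draw_decision <- function(p, r) {
  if (any(p < 0 | p > 1)) stop_("p must lie in [0, 1]")
  if (any(r < 0 | r > 1)) stop_("r must lie in [0, 1]")
  r < p
}

#' Draw a category from a discrete risk equation by inverse transform
#'
#' Returns the first category (in the equation's fixed declared order) whose
#' cumulative probability exceeds `r`; at `r = 0` this is the first category
#' with non-zero probability.
#'
#' @param eq `mlogit` or `ologit` `risk_equation`
#' @param x named covariate vector
#' @param r uniform draw in \[0, 1)
#' @return category label (character)
#' @export
draw_categorical <- function(eq, x = numeric(0), r) {
  if (r < 0 || r >= 1) stop_("r must lie in [0, 1)")
  p <- category_probs(eq, x)
  cum <- cumsum(p)
  k <- which(cum > r)[1]
  if (is.na(k)) k <- length(p)  # guard against rounding at the top end
  names(p)[k]
}
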