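# Precomputed per-equation fast paths for the simulation engine.
#
# The exported primitives (survival_value, conditional_event_time,
# draw_decision, draw_categorical) are the reference implementations; the
# engine walks millions of draws, so each equation is compiled once per
# cohort into integer term indices over a fixed covariate layout plus its
# closed-form inverse sampler. Tests assert the fast path reproduces the
# reference primitives draw for draw.

build_engine_cache <- function(coeffs) {
  terms <- unique(unlist(lapply(coeffs$equations, `[[`, "term_names")))
  for (t in c("lot_c", "bcr_prev2", "bcr_prev3", "post_asct"))
    if (!t %in% terms) terms <- c(terms, t)
  eqs <- lapply(names(coeffs$equations), function(key) {
    eq <- coeffs$equations[[key]]
    tn <- eq$term_names
    has_int <- !is.null(names(eq$beta)) && "(Intercept)" %in% names(eq$beta)
    ec <- list(
      family = eq$family,
      b0 = if (has_int) unname(eq$beta[["(Intercept)"]]) else 0,
      idx = match(tn, terms),
      bv = if (length(tn)) unname(eq$beta[tn]) else numeric(0),
      curtail = {
        cm <- if (key %in% names(coeffs$curtailments))
          coeffs$curtailments[[key]] else NULL
        if (is.null(cm) || !is.finite(cm)) Inf else cm
      })
    anc <- eq$ancillary
    if (eq$family %in% c("gompertz", "weibull")) ec$shape <- anc$shape
    if (eq$family == "weibull_spline3") {
      ec$knots <- anc$knots; ec$gamma <- anc$gamma
    }
    if (eq$family == "ologit") {
      ec$cutpoints <- anc$cutpoints; ec$levels <- anc$levels
    }
    if (eq$family == "mlogit") {
      cm <- anc$coef
      ec$coefm <- unname(rbind(0, cm[, c("(Intercept)", tn), drop = FALSE]))
      ec$levels <- anc$levels
    }
    ec
  })
  names(eqs) <- names(coeffs$equations)
  list(terms = terms, eqs = eqs)
}

fast_eta <- function(ec, x) {
  if (length(ec$idx)) ec$b0 + sum(ec$bv * x[ec$idx]) else ec$b0
}

# scalar natural-cubic-spline evaluation and derivative on log time
srcs <- function(z, knots, gamma) {
  kmin <- knots[1]; kmax <- knots[length(knots)]
  s <- gamma[1] + gamma[2] * z
  r <- kmax - kmin
  for (j in seq_along(knots)[-c(1, length(knots))]) {
    lam <- (kmax - knots[j]) / r
    s <- s + gamma[j + 1] * (max(z - knots[j], 0)^3 -
                               lam * max(z - kmin, 0)^3 -
                               (1 - lam) * max(z - kmax, 0)^3)
  }
  s
}
dsrcs <- function(z, knots, gamma) {
  kmin <- knots[1]; kmax <- knots[length(knots)]
  s <- gamma[2]
  r <- kmax - kmin
  for (j in seq_along(knots)[-c(1, length(knots))]) {
    lam <- (kmax - knots[j]) / r
    s <- s + 3 * gamma[j + 1] * (max(z - knots[j], 0)^2 -
                                   lam * max(z - kmin, 0)^2 -
                                   (1 - lam) * max(z - kmax, 0)^2)
  }
  s
}

# invert s(z) = target by Newton (s is linear outside the boundary knots)
solve_spline_z <- function(target, knots, gamma) {
  z <- (target - gamma[1]) / gamma[2]
  for (i in 1:50) {
    f <- srcs(z, knots, gamma) - target
    if (abs(f) < 1e-12) return(z)
    d <- dsrcs(z, knots, gamma)
    if (!is.finite(d) || d <= 0) break
    z <- z - f / d
  }
  f <- function(zz) srcs(zz, knots, gamma) - target
  lo <- knots[1] - 50; hi <- knots[length(knots)] + 50
  if (f(hi) < 0) return(Inf)
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

# conditional inverse-transform sampling, cached-equation version
fast_cond_time <- function(ec, eta, t0, u) {
  if (ec$family == "gompertz") {
    lam <- exp(eta)
    g <- ec$shape
    H0 <- if (t0 > 0) lam * gomp_g(t0, g) else 0
    Htar <- H0 - log(u)
    if (abs(g) < 1e-9) return(Htar / lam * (1 - g * Htar / (2 * lam)))
    arg <- g * Htar / lam
    if (arg <= -1) return(Inf)
    return(log1p(arg) / g)
  }
  if (ec$family == "weibull") {
    lam <- exp(eta)
    Htar <- (if (t0 > 0) lam * t0^ec$shape else 0) - log(u)
    return((Htar / lam)^(1 / ec$shape))
  }
  # spline on log cumulative hazard (state clocks start at 0)
  H0 <- if (t0 > 0) exp(srcs(log(t0), ec$knots, ec$gamma) + eta) else 0
  Htar <- H0 - log(u)
  exp(solve_spline_z(log(Htar) - eta, ec$knots, ec$gamma))
}

fast_cat <- function(ec, x, r) {
  if (ec$family == "ologit") {
    eta <- fast_eta(ec, x)
    cum <- c(stats::plogis(ec$cutpoints - eta), 1)
  } else {
    xi <- c(1, if (length(ec$idx)) x[ec$idx] else numeric(0))
    e <- drop(ec$coefm %*% xi)
    p <- exp(e - max(e))
    cum <- cumsum(p / sum(p))
  }
  ec$levels[min(sum(cum <= r) + 1, length(ec$levels))]
}
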