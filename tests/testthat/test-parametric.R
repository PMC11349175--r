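test_that("survival functions start at 1 and match hazard quadrature", {
  gomp <- plain_eq("gompertz", log(0.1), 0.05)
  weib <- plain_eq("weibull", log(0.05), 1.4)
  expect_equal(survival_value(0, gomp), 1)
  expect_equal(survival_value(0, weib), 1)
  # S(t) = exp(-integral of the hazard)
  for (t in c(2, 10, 25)) {
    Hg <- stats::integrate(function(u) 0.1 * exp(0.05 * u), 0, t,
                           rel.tol = 1e-12)$value
    expect_equal(survival_value(t, gomp), exp(-Hg), tolerance = 1e-6)
    Hw <- stats::integrate(function(u) 0.05 * 1.4 * u^0.4, 0, t,
                           rel.tol = 1e-12)$value
    expect_equal(survival_value(t, weib), exp(-Hw), tolerance = 1e-6)
  }
})

test_that("a vanishing Gompertz shape reduces to the exponential", {
  eq <- plain_eq("gompertz", log(0.07), 1e-12)
  for (t in c(1, 5, 20, 80)) {
    expect_equal(survival_value(t, eq), exp(-0.07 * t), tolerance = 1e-8)
  }
})

test_that("conditional sampling inverts the conditional survival exactly", {
  gomp <- plain_eq("gompertz", log(0.1), 0.05)
  t1 <- conditional_event_time(gomp, t0 = 12, u = 0.5)
  root <- stats::uniroot(function(t) survival_value(t, gomp) -
                           0.5 * survival_value(12, gomp),
                         c(12, 500), tol = 1e-12)$root
  expect_equal(t1, root, tolerance = 1e-8)
  # u -> 1 at t0 = 0 gives t -> 0
  expect_lt(conditional_event_time(gomp, t0 = 0, u = 1 - 1e-12), 1e-8)
  # spline family: S(t) = u * S(t0) by construction
  sp <- ground_truth_coefficients()$equations$dur_lot1_asct
  x <- c(age_dec = 0.4, male = 1)
  ts <- conditional_event_time(sp, x, t0 = 2, u = 0.37)
  expect_equal(survival_value(ts, sp, x) / survival_value(2, sp, x), 0.37,
               tolerance = 1e-8)
  expect_error(conditional_event_time(gomp, t0 = 0, u = 0), "strictly")
  expect_error(conditional_event_time(gomp, t0 = 0, u = 1), "strictly")
})

test_that("negative Gompertz shape yields a surviving fraction and Inf draws", {
  eq <- plain_eq("gompertz", log(0.05), -0.08)
  splateau <- exp(exp(log(0.05)) / -0.08)
  expect_equal(survival_value(1e6, eq), splateau, tolerance = 1e-10)
  expect_identical(conditional_event_time(eq, t0 = 0, u = splateau * 0.9),
                   Inf)
})

test_that("exponential durations are memoryless under Weibull p = 1", {
  eq <- plain_eq("weibull", log(0.2), 1)
  set.seed(71)
  u <- runif(1e5)
  draws <- vapply(u, function(ui)
    conditional_event_time(eq, t0 = 7, u = ui) - 7, numeric(1))
  ks <- suppressWarnings(stats::ks.test(draws, stats::pexp, rate = 0.2))
  expect_gt(ks$p.value, 0.01)
})

test_that("ML fits recover known parameters and agree with flexsurv", {
  skip_if_not_installed("flexsurv")
  set.seed(5)
  n <- 5000
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  lam <- exp(drop(cbind(1, X) %*% c(-4.5, 0.4, -0.3)))
  g <- 0.02
  tt <- log(1 - g * log(runif(n)) / lam) / g
  cens <- runif(n, 0, 150)
  time <- pmin(tt, cens); ev <- as.integer(tt <= cens)
  f <- fit_parametric_survival(time, ev, X, "gompertz")
  ci <- function(k) f$par[k] + c(-1, 1) * 1.96 * sqrt(diag(f$vcov))[k]
  truth <- c("(Intercept)" = -4.5, x1 = 0.4, x2 = -0.3, shape = 0.02)
  for (k in names(truth)) {
    expect_gt(truth[k], ci(k)[1])
    expect_lt(truth[k], ci(k)[2])
  }
  ref <- flexsurv::flexsurvreg(survival::Surv(time, ev) ~ x1 + x2,
                               data = as.data.frame(X), dist = "gompertz")
  expect_equal(unname(f$ancillary$shape), unname(ref$res["shape", "est"]),
               tolerance = 1e-4)
  expect_equal(unname(f$beta[c("x1", "x2")]),
               unname(ref$res[c("x1", "x2"), "est"]), tolerance = 1e-4)
  expect_equal(f$stats$loglik, as.numeric(stats::logLik(ref)),
               tolerance = 1e-6)
  # weibull proportional-hazards fit against flexsurv weibullPH
  p <- 1.5
  tt <- (-log(runif(n)) / lam)^(1 / p)
  time <- pmin(tt, cens); ev <- as.integer(tt <= cens)
  fw <- fit_parametric_survival(time, ev, X, "weibull")
  refw <- flexsurv::flexsurvreg(survival::Surv(time, ev) ~ x1 + x2,
                                data = as.data.frame(X), dist = "weibullPH")
  expect_equal(unname(fw$ancillary$shape), unname(refw$res["shape", "est"]),
               tolerance = 1e-4)
  expect_equal(fw$stats$loglik, as.numeric(stats::logLik(refw)),
               tolerance = 1e-6)
})

test_that("intercept-only fit attains the closed-form exponential MLE", {
  set.seed(9)
  time <- rexp(2000, 0.1)
  ev <- rep(1L, 2000)
  f <- fit_parametric_survival(time, ev, family = "weibull")
  # exponential closed form: rate = events / exposure; the Weibull fit nests
  # it, so its likelihood can only be higher and p should sit near 1
  lam0 <- sum(ev) / sum(time)
  ll0 <- sum(log(lam0)) * sum(ev) - lam0 * sum(time)
  expect_gte(f$stats$loglik, ll0 - 1e-6)
  se_logp <- sqrt(diag(f$vcov))[["log_shape"]]
  expect_lt(abs(log(f$ancillary$shape)) / se_logp, 2.6)
  expect_equal(unname(exp(f$beta[["(Intercept)"]])), lam0, tolerance = 0.05)
})

test_that("fitting without events is refused", {
  expect_error(fit_parametric_survival(c(1, 2, 3), c(0, 0, 0),
                                       family = "weibull"), "no events")
})

test_that("left-truncated fits agree with flexsurv counting-process form", {
  skip_if_not_installed("flexsurv")
  set.seed(12)
  n <- 3000
  x <- rnorm(n)
  lam <- exp(-3.5 + 0.3 * x)
  g <- 0.03
  t0 <- runif(n, 0, 10)
  # draw conditional on survival to t0 via inverse conditional CDF
  u <- runif(n)
  H0 <- lam / g * (exp(g * t0) - 1)
  tt <- log(1 + g * (H0 - log(u)) / lam) / g
  cens <- t0 + runif(n, 0, 60)
  time <- pmin(tt, cens); ev <- as.integer(tt <= cens)
  f <- fit_parametric_survival(time, ev, cbind(x = x), "gompertz",
                               tstart = t0)
  ref <- flexsurv::flexsurvreg(survival::Surv(t0, time, ev) ~ x,
                               data = data.frame(x = x), dist = "gompertz")
  expect_equal(unname(f$ancillary$shape), unname(ref$res["shape", "est"]),
               tolerance = 1e-3)
  expect_equal(unname(f$beta[["x"]]), unname(ref$res["x", "est"]),
               tolerance = 1e-3)
})

test_that("information-criterion selection prefers the generating family", {
  set.seed(31)
  wins <- 0L
  for (r in 1:15) {
    n <- 1500
    lam <- 0.02; g <- 0.06
    tt <- log(1 - g * log(runif(n)) / lam) / g
    cens <- runif(n, 0, 80)
    time <- pmin(tt, cens); ev <- as.integer(tt <= cens)
    fits <- list(fit_parametric_survival(time, ev, family = "gompertz"),
                 fit_parametric_survival(time, ev, family = "weibull"))
    if (select_distribution(fits)$family == "gompertz") wins <- wins + 1L
  }
  expect_gt(wins, 7)
})

test_that("distribution selection breaks ties by family order and passes singletons", {
  set.seed(2)
  time <- rexp(300, 0.2); ev <- rep(1L, 300)
  f1 <- fit_parametric_survival(time, ev, family = "gompertz")
  f2 <- fit_parametric_survival(time, ev, family = "weibull")
  f2$stats$aic <- f1$stats$aic  # forced tie
  expect_identical(select_distribution(list(f2, f1))$family, "gompertz")
  expect_identical(select_distribution(list(f1)), f1)
  cmp <- attr(select_distribution(list(f1, f2)), "comparison")
  expect_identical(nrow(cmp), 2L)
  expect_true(all(c("aic", "bic", "loglik") %in% names(cmp)))
  f3 <- fit_parametric_survival(time[-1], ev[-1], family = "weibull")
  expect_error(select_distribution(list(f1, f3)), "different data")
})

test_that("the spline family nests and improves on the Weibull fit", {
  set.seed(44)
  n <- 3000
  # change-point hazard: early rate much higher than late
  tt <- ifelse(runif(n) < 0.6, rweibull(n, 3, 4), 6 + rexp(n, 0.05))
  cens <- runif(n, 0, 100)
  time <- pmin(tt, cens); ev <- as.integer(tt <= cens)
  fw <- fit_parametric_survival(time, ev, family = "weibull")
  fs <- fit_parametric_survival(time, ev, family = "weibull_spline3")
  expect_gte(fs$stats$loglik, fw$stats$loglik - 1e-6)
  expect_lt(fs$stats$aic, fw$stats$aic)
  # survival evaluation from the cumulative-hazard representation is a
  # proper survival function
  tgrid <- seq(0, 40, by = 0.5)
  s <- survival_value(tgrid, fs)
  expect_equal(s[1], 1)
  expect_true(all(diff(s) <= 1e-12))
})
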