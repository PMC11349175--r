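---
title: "Modelling multiple myeloma treatment pathways by discrete-event simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multiple myeloma treatment pathways by discrete-event simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Multiple myeloma is treated with successive lines of chemotherapy (LoT),
with or without autologous stem-cell transplantation (ASCT) after induction,
and remains incurable: patients cycle through treatment and treatment-free
intervals until death. `myelosim` implements an individual-patient
discrete-event simulation of this pathway. Time is continuous (months since
diagnosis); each patient carries four diagnostic covariates — age, sex, ECOG
performance status (0 / 1 / 2+, the high-morbidity categories merged) and
ISS stage — plus an evolving treatment history: current line number, best
clinical response (BCR) to the latest treatment, and transplant status.

The pathway is driven by 30 risk equations, each a regression with its own
covariate list:

* **Time-to-event equations** are parametric proportional-hazards models,
  `h(t | x) = h0(t) exp(x'b)`: a Gompertz baseline
  (`h0(t) = lambda e^(gamma t)`) for overall survival, Weibull baselines
  (`h0(t) = lambda p t^(p-1)`) for chemotherapy durations, treatment-free
  intervals, the diagnosis-to-first-treatment interval, the ASCT episode,
  and the maintenance clock, and a flexible 3-interior-knot natural cubic
  spline on the log cumulative hazard for induction duration under planned
  ASCT, whose hazard changes too quickly for a Weibull.
* **Decision equations** are binary logits (planned ASCT, ASCT receipt,
  maintenance receipt), a multinomial logit over the named regimen catalog
  for LoT 1 and LoT 2 (regimens used by at least 10% of treated patients at
  that line; all others pooled as "other"; from LoT 3 onward patients
  receive the average regimen), and cumulative ordered logits
  `P(Y <= k | x) = logistic(tau_k - x'b)` for BCR, with Complete Response
  the best category.

BCR is six-level (CR, VGPR, PR, MR, SD, PD) through LoT 3 and for ASCT, and
collapsed to three levels (CR/VGPR, PR/MR, SD/PD) from LoT 4, where registry
counts thin out. Lines 6–9 share one equation per outcome. Patients whose
induction response is SD or PD are ineligible for transplant. Maintenance
therapy does not improve response; it only lengthens the LoT 1 to LoT 2
interval.

### Scheduling

Overall survival is re-predicted at the entry of every health state by
conditional inverse-transform sampling: a uniform draw `u` on (0, 1) is
mapped through `S(t) = u * S(t0)` given the patient's current covariates,
which for the Gompertz and Weibull families inverts in closed form. The
fresh draw supersedes the previous one (it conditions on survival to the
state entry, so the marginal law is unchanged when covariates are unchanged)
and competes with the state's duration: whichever event comes first wins,
and death wins exact ties. Durations and intervals are curtailed at the
maximum observed in the estimation data, and any event beyond age 100 is
curtailed to an age-cap terminal event, analysed as death at the cap.
Binary decisions occur when `r < p` for a uniform `r` — the convention is
equivalent in distribution to its mirror image for a single draw.

### The 30-equation enumeration

The default enumeration is: overall survival (1); diagnosis-to-first-
treatment (1); planned-ASCT, ASCT-receipt and maintenance-receipt logits
(3); regimen multinomials for LoT 1–2 (2); BCR ordered logits for LoT 1,
ASCT, LoT 2–5 and shared LoT 6–9 (7); chemotherapy durations for LoT 1
planned-ASCT (spline), LoT 1 non-ASCT, LoT 2–5 and shared LoT 6–9 (7); the
ASCT episode duration (1); treatment-free intervals after LoT 1 (ASCT and
non-ASCT), LoT 2–5 and shared LoT 6–9 (7); and the maintenance clock (1).
The two state-occupancy equations (diagnosis-to-first-treatment and ASCT
episode duration) complete the count of 30: both are real clocks in the
pathway — registries record treatment starting weeks after diagnosis, and
the transplant episode occupies time between induction and maintenance —
and both are estimable from the line table. Maintenance is modelled as
treatment-until-next-line (standard practice in myeloma), so the
maintenance clock is fitted on the LoT 1 to LoT 2 gap of maintained
patients while the two explicit LoT 1 to LoT 2 interval equations are
fitted on non-maintained patients; this realizes "maintenance lengthens
only the LoT 1 to LoT 2 interval" with a separate duration equation rather
than a covariate, and the engine draws whichever clock applies. The
enumeration, covariate lists, and regimen catalogs are configuration, not
code (`framework_config()`), and an audit test pins the count at 30.

### Estimating the overall-survival equation

A single OS equation is re-evaluated at every state entry, so it is fitted
on *health-state entry episodes*: one left-truncated counting-process row
per interval between covariate changes (line starts update the line number;
treatment ends update the response; transplant completion sets the
transplant flag), with the death or censoring landing on the patient's last
episode. The episode likelihood — `d log h(t_stop) - (H(t_stop) -
H(t_start))` per row — is then exactly the likelihood of the piecewise
hazard the engine simulates from; fitting and simulation cannot drift
apart. A line that ends exactly at the end of follow-up with no assessed
response ended because the patient died (or the database closed), so its
duration is censored rather than counted as a completed treatment, and the
maintenance-receipt model conditions on surviving induction.

## Missing data

ECOG (~29%), ISS (~27%) and BCR (~27–29%) are imputed by chained equations:
ordinal logistic models, cycling ECOG and ISS against each other plus age,
sex and the log laboratory markers, and BCR at the line level on the
6-level scale from the within-line log-ratio changes in paraprotein and
kappa/lambda free light chains plus line number. The BCR model's predictors
are fully observed, so it needs a single pass; the default of 5 sweeps for
the patient-level pair follows the convention of chained-equation software
(two weakly coupled variables converge immediately; drift of imputed
category frequencies across sweeps is the diagnostic to watch if the model
set is extended). Imputation is proper — conditional-model coefficients are
drawn from their approximate normal posterior before each predictive draw —
and observed cells are never altered. Each equation is estimated on every
completed dataset (default m = 10) and pooled by Rubin's rules: pooled
estimate = mean, total variance `T = W + (1 + 1/m) B`, degrees of freedom
`(m - 1)(1 + W / ((1 + 1/m) B))^2`.

Chemotherapy lines with no recorded end date that must have ended — the
patient died or started a later line — are dropped before estimation, since
treating them as long censored durations would skew the duration equations;
unended lines with no later event are kept as ongoing, censored at last
follow-up.

## The synthetic registry

The real registry is confidential, so the generator produces registries
with known ground truth: diagnostic profiles matching the published
marginals (age 67.3 ± 11.6 truncated to 18–100, 60.4% male, ECOG
42.9/36.9/20.2% and ISS 29.3/41.7/29.0% among non-missing), complete
trajectories simulated under a fixed plausible coefficient set
(`ground_truth_coefficients()`: median overall survival near six years,
4–6 month treatment durations, intervals that shorten with line number and
worsen with poorer response), administrative censoring uniform over a 6–174
month accrual window (roughly the 2009–2023 accrual of a registry frozen in
2024), and the published missingness injected afterwards: MAR masks for
ECOG/ISS whose probability rises with observed age, 29% / 26.6% masking of
assessed chemotherapy / ASCT responses, and 4% of completed chemotherapy
lines losing their end date (about the 300 in 7,500 reported for the real
registry). Within-line laboratory changes are generated from the true
response plus noise, which is what makes the masked responses imputable.
Ground-truth values ride along as an attribute for recovery tests.

What the generator does *not* emulate: site structure and data-entry drift,
calendar-time treatment changes, correlation between ECOG and ISS at
diagnosis (generated independently; the published table gives marginals
only), comorbidities, and any dependence of the missingness on unobserved
values (the masks are MAR by construction). Passing self-consistency
validation on this registry therefore demonstrates that estimation,
imputation, simulation and comparison are mutually consistent at realistic
scale and missingness — not that the fitted model transports to real
registry data.

## Out-of-sample validation

`bootstrap_validate()` implements the out-of-sample design: a patient-level
70/30 split; per bootstrap replicate the training cohort is resampled with
replacement and the *entire* estimation pipeline is re-run (imputation,
all 30 equations, Rubin pooling), then a cohort is simulated whose
diagnostic profiles are resampled from the imputed validation cohort, and
monthly overall survival for months 1–120 is read off the Kaplan–Meier
curves of the (resampled) validation cohort and the simulated cohort. For
each month, `c` counts replicates in which validation survival exceeds
simulated survival — exact ties count one half — and the two-sided
bootstrap sign p-value is `min(1, 2 min(c, B - c) / B)`, which reproduces
the worked examples (c = 50, B = 100 gives 1; c = 5 gives 0.1); the
literal expression `2c/B` exceeds 1 for c > B/2, so the symmetric two-sided
form is used. The headline summary is the percentage of the 120 months
with p >= 0.05. Survival-by-response tables (median and quartiles, in
years, "not reached" when a quantile exceeds follow-up) stratify by BCR to
LoT 1 for non-transplanted and BCR to ASCT for transplanted patients.

The defaults are registry-study scale (B = 100, m = 10, 10,000 simulated
patients). The package's own self-consistency experiment — an acceptance
test and `scripts/acceptance.R` — runs the full pipeline at a reduced scale
chosen to keep a complete run on a single core comfortable: a 4,121-patient
registry, B = 50, m = 5, 2,000 simulated patients per replicate. At that
scale the bootstrap sign p-value at a month is below 0.05 only when at most
one replicate disagrees with the majority direction, so the >= 90%
non-significant criterion tests for systematic divergence, not noise.

## Numerical choices

* Gompertz quantities use `expm1`/`log1p` forms with a series fallback below
  `|gamma| < 1e-9`; the shape is unconstrained (a negative shape implies a
  survival plateau `exp(lambda/gamma)`; conditional draws below it return
  `Inf` and the caller curtails).
* The Weibull shape is estimated on the log scale; the spline fit starts
  from the nested Weibull solution (so its likelihood can only improve),
  with interior knots at the 25/50/75 percentiles of log event times and
  boundary knots at the range, fixed across imputations so pooling is
  well-defined. Non-monotone spline regions are rejected with a likelihood
  penalty.
* Fits use BFGS with analytic gradients (relative tolerance 1e-9) and
  report observed-information variances; the engine pre-compiles each
  equation to integer covariate indices and closed-form samplers, and tests
  pin the fast path to the reference primitives draw for draw.
* Within a state the covariate set is pruned of constant columns (their
  coefficients are not identifiable there); a state whose fit still fails
  falls back to an intercept-only equation with a warning rather than
  aborting a bootstrap replicate. Ordered-logit states drop levels that are
  unobserved in a given bootstrap sample; pooling uses the majority
  parameter layout.
* Every stochastic stage derives its own seed from the master seed
  (`derive_seed()`), and each simulated patient gets an independent
  substream, so results are reproducible and independent of iteration
  order.

## Known limitations

Second transplants, ASCT or maintenance after later lines, cytogenetic risk
(R-ISS), site effects and calendar drift are out of scope in this version
of the framework. The per-equation covariate lists are the package's own
clinically plausible defaults and are fully configurable. The age-cap terminal event is analysed as death at the cap;
with the default accrual window it affects well under 1% of simulated
patients. Imputation models do not condition on the survival outcome, which
attenuates covariate effects slightly when missingness is heavy; the
self-consistency validation shows the effect is not large enough to
separate observed from simulated survival curves at registry scale.
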