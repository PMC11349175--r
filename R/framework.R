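# Framework configuration: the enumeration of risk equations the model
# estimates and the simulation engine visits, plus the shared covariate-term
# dictionary used identically at estimation time (building design matrices)
# and at simulation time (building per-patient covariate vectors), so the two
# sides can never drift apart.
#
# Equation keys and the state sharing rules:
#   * one overall-survival equation, re-evaluated at every health-state entry
#     with updated line number / response / transplant covariates;
#   * lines of therapy 6-9 share a single equation per outcome;
#   * best clinical response is modelled on the 6-level scale through LoT 3
#     (and for ASCT) and on the collapsed 3-level scale from LoT 4;
#   * induction (LoT 1) duration and the LoT1->LoT2 treatment-free interval
#     are split by transplant status; induction duration under planned ASCT
#     uses the 3-interior-knot spline family;
#   * maintained patients' LoT1->LoT2 gap has its own duration equation
#     (maintenance continues until next treatment), which is how maintenance
#     lengthens only that interval.

base_terms <- function() c("age_dec", "male", "ecog1", "ecog2plus", "iss2", "iss3")

regimen_terms <- function(catalog) {
  if (length(catalog) < 2) return(character(0))
  paste0("regimen:", catalog[-1])  # first catalog entry is the reference
}

#' Framework configuration: the risk-equation enumeration
#'
#' Builds the default enumeration of 30 risk equations: overall survival;
#' time from diagnosis to first treatment; planned-ASCT, ASCT-receipt and
#' maintenance-receipt logits; regimen multinomial logits for LoT 1 and 2;
#' best-clinical-response ordered logits for LoT 1, ASCT, LoT 2-5 and shared
#' LoT 6-9; chemotherapy duration for LoT 1 (planned-ASCT spline and
#' non-ASCT), LoT 2-5 and shared LoT 6-9; ASCT episode duration; the
#' treatment-free intervals after LoT 1 (ASCT and non-ASCT), LoT 2-5 and
#' shared LoT 6-9; and maintenance duration.
#'
#' @param lot1_catalog,lot2_catalog named regimen catalogs (first entry =
#'   reference level; see [regimen_catalog()])
#' @param max_lot maximum line of therapy (<= 9)
#' @return a `framework_config` list with one definition per equation
#' @export
framework_config <- function(lot1_catalog = c("other", "VRd", "VCd", "Rd"),
                             lot2_catalog = c("other", "Rd", "DVd"),
                             max_lot = 9) {
  stopifnot(max_lot >= 2, max_lot <= 9)
  bt <- base_terms()
  eq <- function(key, outcome, state, family, terms, levels = NULL) {
    list(key = key, outcome = outcome, state = state, family = family,
         terms = terms, levels = levels)
  }
  bcr6 <- bcr_levels()
  bcr3 <- c("1", "2", "3")
  defs <- list(
    eq("os", "os", "all", "gompertz",
       c(bt, "lot_c", "bcr_prev2", "bcr_prev3", "post_asct")),
    eq("tt_first", "tt_first", "diagnosis", "weibull", bt),
    eq("planned_asct", "planned_asct", "lot1", "logit", bt),
    eq("asct_receipt", "asct_receipt", "lot1", "logit",
       c("age_dec", "male", "bcr_prev2")),
    eq("maintenance_receipt", "maintenance_receipt", "lot1", "logit",
       c("age_dec", "male", "post_asct")),
    eq("regimen_lot1", "regimen", "lot1", "mlogit",
       c("age_dec", "male", "ecog1", "ecog2plus"), levels = lot1_catalog),
    eq("regimen_lot2", "regimen", "lot2", "mlogit",
       c("age_dec", "male", "ecog1", "ecog2plus"), levels = lot2_catalog),
    eq("bcr_lot1", "bcr", "lot1", "ologit",
       c(bt, regimen_terms(lot1_catalog)), levels = bcr6),
    eq("bcr_asct", "bcr", "asct", "ologit",
       c("age_dec", "bcr_prev2"), levels = bcr6),
    eq("bcr_lot2", "bcr", "lot2", "ologit",
       c(bt, "bcr_prev2", "bcr_prev3", regimen_terms(lot2_catalog)),
       levels = bcr6),
    eq("bcr_lot3", "bcr", "lot3", "ologit",
       c(bt, "bcr_prev2", "bcr_prev3"), levels = bcr6),
    eq("bcr_lot4", "bcr", "lot4", "ologit",
       c("age_dec", "male", "bcr_prev2", "bcr_prev3"), levels = bcr3),
    eq("bcr_lot5", "bcr", "lot5", "ologit",
       c("age_dec", "male", "bcr_prev2", "bcr_prev3"), levels = bcr3),
    eq("bcr_lot6_9", "bcr", "lot6_9", "ologit",
       c("age_dec", "bcr_prev2", "bcr_prev3", "lot_c"), levels = bcr3),
    eq("dur_lot1_asct", "chemo_duration", "lot1_asct", "weibull_spline3",
       c("age_dec", "male")),
    eq("dur_lot1_noasct", "chemo_duration", "lot1_noasct", "weibull",
       c(bt, regimen_terms(lot1_catalog))),
    eq("dur_lot2", "chemo_duration", "lot2", "weibull",
       c("age_dec", "male", "iss2", "iss3", regimen_terms(lot2_catalog))),
    eq("dur_lot3", "chemo_duration", "lot3", "weibull",
       c("age_dec", "male", "ecog1", "ecog2plus")),
    eq("dur_lot4", "chemo_duration", "lot4", "weibull",
       c("age_dec", "male", "ecog1", "ecog2plus")),
    eq("dur_lot5", "chemo_duration", "lot5", "weibull",
       c("age_dec", "male")),
    eq("dur_lot6_9", "chemo_duration", "lot6_9", "weibull",
       c("age_dec", "male", "lot_c")),
    eq("dur_asct", "asct_duration", "asct", "weibull", "age_dec"),
    eq("tfi_lot1_asct", "tfi", "lot1_asct", "weibull",
       c("age_dec", "male", "bcr_prev2", "bcr_prev3")),
    eq("tfi_lot1_noasct", "tfi", "lot1_noasct", "weibull",
       c("age_dec", "male", "bcr_prev2", "bcr_prev3")),
    eq("tfi_lot2", "tfi", "lot2", "weibull",
       c("age_dec", "bcr_prev2", "bcr_prev3")),
    eq("tfi_lot3", "tfi", "lot3", "weibull",
       c("age_dec", "bcr_prev2", "bcr_prev3")),
    eq("tfi_lot4", "tfi", "lot4", "weibull",
       c("age_dec", "bcr_prev2", "bcr_prev3")),
    eq("tfi_lot5", "tfi", "lot5", "weibull", c("age_dec", "bcr_prev2")),
    eq("tfi_lot6_9", "tfi", "lot6_9", "weibull",
       c("age_dec", "bcr_prev2", "bcr_prev3", "lot_c")),
    eq("dur_maintenance", "maintenance_duration", "lot1", "weibull",
       c("age_dec", "bcr_prev2", "bcr_prev3", "post_asct"))
  )
  names(defs) <- vapply(defs, `[[`, character(1), "key")
  structure(list(equations = defs, lot1_catalog = lot1_catalog,
                 lot2_catalog = lot2_catalog, max_lot = max_lot),
            class = "framework_config")
}

#' @export
print.framework_config <- function(x, ...) {
  cat(sprintf("<framework_config> %d risk equations, max LoT %d\n",
              length(x$equations), x$max_lot))
  cat(sprintf("  LoT 1 regimens: %s\n", paste(x$lot1_catalog, collapse = ", ")))
  cat(sprintf("  LoT 2 regimens: %s\n", paste(x$lot2_catalog, collapse = ", ")))
  invisible(x)
}

#' Regimen catalog under the 10%-use rule
#'
#' Named regimens used by at least `threshold` (default 10%) of the patients
#' treated at the given line; all others are pooled as `"other"`, which is
#' also the reference category.
#'
#' @param table a `registry_table` (unimputed; regimen is never imputed)
#' @param lot line of therapy (1 or 2)
#' @param threshold minimum usage fraction
#' @return character vector of regimen labels, `"other"` first
#' @export
regimen_catalog <- function(table, lot, threshold = 0.1) {
  l <- table$lines
  reg <- l$regimen[!l$is_asct & !is.na(l$lot) & l$lot == lot]
  if (!length(reg)) return("other")
  tab <- table(reg[reg != "other"])
  keep <- names(tab)[tab / length(reg) >= threshold]
  c("other", sort(keep))
}

# ---- covariate-term dictionary ------------------------------------------

# ctx: data.frame (or one-row list) with columns
#   age_dx, sex, ecog, iss, lot, bcr_prev (0 = none, else collapsed 1:3),
#   post_asct, regimen
term_columns <- function(ctx, terms) {
  n <- length(ctx$age_dx)
  col <- function(term) {
    if (startsWith(term, "regimen:")) {
      lab <- sub("^regimen:", "", term)
      return(as.numeric(ctx$regimen == lab))
    }
    switch(term,
      age_dec = (ctx$age_dx - 65) / 10,
      male = as.numeric(ctx$sex == "male"),
      ecog1 = as.numeric(ctx$ecog == "1"),
      ecog2plus = as.numeric(ctx$ecog == "2plus"),
      iss2 = as.numeric(ctx$iss == 2),
      iss3 = as.numeric(ctx$iss == 3),
      lot_c = pmax(ctx$lot - 1, 0),
      bcr_prev2 = as.numeric(ctx$bcr_prev == 2),
      bcr_prev3 = as.numeric(ctx$bcr_prev == 3),
      post_asct = as.numeric(ctx$post_asct),
      stop_("unknown covariate term '%s'", term))
  }
  m <- vapply(terms, col, numeric(n))
  if (n == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, terms))
  m
}

# named covariate vector for a single simulation context
term_vector <- function(ctx, terms) {
  drop_m <- term_columns(ctx, terms)
  stats::setNames(as.numeric(drop_m[1, ]), terms)
}

# ---- model coefficients container ---------------------------------------

#' Construct a model-coefficients set
#'
#' The complete set of fitted (or ground-truth) risk equations keyed by
#' equation id, together with the duration curtailment maxima (durations and
#' treatment-free intervals are curtailed at the maximum observed in the
#' data) and the regimen catalogs.
#'
#' @param equations named list of `risk_equation`s
#' @param curtailments named numeric vector of maxima (months) keyed by
#'   duration/interval equation id
#' @param config the `framework_config` the equations instantiate
#' @return object of class `model_coefficients`
#' @export
model_coefficients <- function(equations, curtailments, config) {
  need <- names(config$equations)
  miss <- setdiff(need, names(equations))
  if (length(miss))
    stop_("missing risk equation(s): %s", paste(miss, collapse = ", "))
  structure(list(equations = equations[need], curtailments = curtailments,
                 config = config),
            class = "model_coefficients")
}

#' @export
print.model_coefficients <- function(x, ...) {
  cat(sprintf("<model_coefficients> %d risk equations\n", length(x$equations)))
  fam <- table(vapply(x$equations, `[[`, character(1), "family"))
  cat("  ", paste(sprintf("%s: %d", names(fam), fam), collapse = ", "), "\n")
  invisible(x)
}

# Resolve the equation for an (outcome, lot/state) the engine visits.
# Lines 6-9 share one equation per outcome.
equation_key <- function(outcome, lot = NULL, asct = NULL) {
  lot_state <- function(l) if (l >= 6) "lot6_9" else paste0("lot", l)
  switch(outcome,
    os = "os",
    tt_first = "tt_first",
    planned_asct = "planned_asct",
    asct_receipt = "asct_receipt",
    maintenance_receipt = "maintenance_receipt",
    regimen = paste0("regimen_lot", lot),
    bcr = if (isTRUE(asct)) "bcr_asct" else paste0("bcr_", lot_state(lot)),
    chemo_duration = if (lot == 1) {
      if (isTRUE(asct)) "dur_lot1_asct" else "dur_lot1_noasct"
    } else paste0("dur_", lot_state(lot)),
    asct_duration = "dur_asct",
    tfi = if (lot == 1) {
      if (isTRUE(asct)) "tfi_lot1_asct" else "tfi_lot1_noasct"
    } else paste0("tfi_", lot_state(lot)),
    maintenance_duration = "dur_maintenance",
    stop_("unknown outcome kind '%s'", outcome))
}
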