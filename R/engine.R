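# Discrete-event simulation core: walk one patient from diagnosis to death
# through up to nine lines of therapy.
#
# Scheduling scheme: overall survival is re-predicted at every health-state
# entry by conditional inverse-transform sampling (a uniform draw on
# (0, S(t0)) mapped through the patient's own survival curve given the
# current covariates); the freshly drawn death time supersedes the previous
# one and competes with the state's duration — whichever happens first wins,
# with death winning exact ties. Durations and treatment-free intervals are
# curtailed at the maxima observed in the estimation data; any event beyond
# age 100 is curtailed to an age-cap terminal event (analyzed as death at
# the cap).

#' Simulation configuration
#'
#' @param n_patients number of patients to simulate (cohort runs)
#' @param seed master seed; every patient gets an independent derived stream
#' @param max_lot maximum line of therapy (default 9)
#' @param age_cap age (years) beyond which survival is curtailed (default 100)
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(n_patients = 10000, seed = 1, max_lot = 9,
                              age_cap = 100) {
  stopifnot(n_patients >= 0, max_lot >= 1, max_lot <= 9, age_cap > 18)
  structure(list(n_patients = n_patients, seed = seed, max_lot = max_lot,
                 age_cap = age_cap), class = "simulation_config")
}

curtail_max <- function(coeffs, key) {
  cm <- coeffs$curtailments[[key]]
  if (is.null(cm) || !is.finite(cm)) Inf else cm
}

#' Simulate one patient's trajectory
#'
#' Executes the pathway: planned-ASCT decision, LoT-1 regimen and induction
#' duration (spline equation if ASCT is planned), best clinical response,
#' ASCT receipt (patients whose induction response is Stable or Progressive
#' Disease are ineligible), maintenance receipt (which lengthens only the
#' LoT1->LoT2 interval), then alternating treatment-free intervals and
#' further lines up to `max_lot`, with response collapsed to the 3-level
#' scale from LoT 4 and LoT 6-9 sharing equations. Overall survival is
#' re-drawn at every health-state entry conditional on survival so far and
#' competes with every state duration.
#'
#' Uses the current RNG stream; [simulate_cohort()] seeds an independent
#' stream per patient.
#'
#' @param profile list or one-row data frame with fully observed
#'   `age_dx, sex, ecog, iss` (post-imputation)
#' @param coeffs a `model_coefficients` set
#' @param config a `simulation_config`
#' @return a `trajectory`: data frame of (time, event, detail) with
#'   attributes `os_months`, `terminal` ("death" or "age_cap"), `bcr_first`
#'   (response to LoT 1 for non-ASCT patients, to ASCT for ASCT patients),
#'   `n_lots`, and `lines` (the treatment rows in registry layout)
#' @export
simulate_patient <- function(profile, coeffs, config = simulation_config()) {
  for (f in c("age_dx", "sex", "ecog", "iss")) {
    v <- profile[[f]]
    if (is.null(v) || is.na(v)) stop_("profile field '%s' is missing", f)
  }
  # flat covariate vector over the union of all equations' terms, updated
  # in place as the patient moves through the pathway; equations are
  # pre-compiled to integer indices into this layout
  cache <- attr(coeffs, "engine_cache") %||% build_engine_cache(coeffs)
  all_terms <- cache$terms
  reg_terms <- all_terms[startsWith(all_terms, "regimen:")]
  x <- term_vector(list(age_dx = profile$age_dx, sex = profile$sex,
                        ecog = profile$ecog, iss = profile$iss, lot = 0,
                        bcr_prev = 0, post_asct = FALSE, regimen = "other"),
                   all_terms)
  set_lot <- function(lot) x["lot_c"] <<- max(lot - 1, 0)
  set_bcr <- function(b3) {
    x["bcr_prev2"] <<- as.numeric(b3 == 2)
    x["bcr_prev3"] <<- as.numeric(b3 == 3)
  }
  set_regimen <- function(reg) {
    if (length(reg_terms)) {
      x[reg_terms] <<- 0
      hit <- paste0("regimen:", reg)
      if (hit %in% reg_terms) x[hit] <<- 1
    }
  }
  cap_t <- (config$age_cap - profile$age_dx) * 12
  os_ec <- cache$eqs[["os"]]
  if (is.null(os_ec)) stop_("no risk equation for key 'os'")
  ev_time <- numeric(64); ev_lab <- character(64); ev_det <- character(64)
  nev <- 0L
  note <- function(t, lab, det = "") {
    nev <<- nev + 1L
    ev_time[nev] <<- t; ev_lab[nev] <<- lab; ev_det[nev] <<- det
  }
  # line accumulators (registry layout)
  nl <- 0L
  ln_lot <- integer(12); ln_reg <- character(12); ln_start <- numeric(12)
  ln_end <- numeric(12); ln_asct <- logical(12); ln_planned <- logical(12)
  ln_maint <- logical(12); ln_bcr <- character(12)
  add_line <- function(lot, regimen, start, end, is_asct, planned, bcr) {
    nl <<- nl + 1L
    ln_lot[nl] <<- lot; ln_reg[nl] <<- regimen; ln_start[nl] <<- start
    ln_end[nl] <<- end; ln_asct[nl] <<- is_asct; ln_planned[nl] <<- planned
    ln_maint[nl] <<- FALSE; ln_bcr[nl] <<- bcr
  }
  runif1 <- function() min(max(stats::runif(1), 1e-12), 1 - 1e-12)
  get_ec <- function(key) {
    ec <- cache$eqs[[key]]
    if (is.null(ec)) stop_("no risk equation for key '%s'", key)
    ec
  }
  draw_death <- function(t0) {
    d <- fast_cond_time(os_ec, fast_eta(os_ec, x), t0, runif1())
    min(d, cap_t)
  }
  draw_dur <- function(key) {
    ec <- get_ec(key)
    d <- fast_cond_time(ec, fast_eta(ec, x), 0, runif1())
    min(d, ec$curtail)
  }
  draw_flag <- function(key) {
    ec <- get_ec(key)
    stats::runif(1) < stats::plogis(fast_eta(ec, x))
  }
  draw_cat <- function(key) fast_cat(get_ec(key), x, runif1())
  finish <- function(t_death) {
    terminal <- if (t_death >= cap_t) "age_cap" else "death"
    note(min(t_death, cap_t), terminal)
    i <- seq_len(nev)
    ev <- structure(list(time = ev_time[i], event = ev_lab[i],
                         detail = ev_det[i]),
                    names = c("time", "event", "detail"),
                    row.names = c(NA, -nev),
                    class = c("trajectory", "data.frame"))
    ln <- NULL
    if (nl) {
      j <- seq_len(nl)
      lot <- ln_lot[j]; planned <- ln_planned[j]
      lot[ln_asct[j]] <- NA_integer_
      planned[ln_asct[j]] <- NA
      ln <- structure(list(lot = lot, regimen = ln_reg[j],
                           start_time = ln_start[j], end_time = ln_end[j],
                           is_asct = ln_asct[j], asct_planned = planned,
                           maintenance = ln_maint[j], bcr = ln_bcr[j]),
                      row.names = c(NA, -nl), class = "data.frame")
    }
    attr(ev, "os_months") <- min(t_death, cap_t)
    attr(ev, "terminal") <- terminal
    attr(ev, "bcr_first") <- bcr_first_val
    attr(ev, "n_lots") <- n_lots
    attr(ev, "lines") <- ln
    ev
  }
  bcr_first_val <- NA_character_
  n_lots <- 0L
  t <- 0
  note(0, "diagnosis")
  death <- draw_death(0)

  # diagnosis -> first treatment
  gap <- draw_dur("tt_first")
  if (death <= t + gap) return(finish(death))
  t <- t + gap
  planned <- draw_flag("planned_asct")
  maint <- FALSE
  for (lot in seq_len(config$max_lot)) {
    set_lot(lot)
    regimen <- if (lot <= 2) draw_cat(equation_key("regimen", lot)) else "other"
    set_regimen(regimen)
    death <- draw_death(t)
    note(t, "lot_start", sprintf("lot%d:%s", lot, regimen))
    n_lots <- lot
    start <- t
    durkey <- equation_key("chemo_duration", lot, asct = planned)
    dur <- draw_dur(durkey)
    if (death <= t + dur) {
      # death during treatment: the line ends at death, no response assessed
      add_line(lot, regimen, start, min(death, cap_t), FALSE,
               lot == 1 && planned, NA)
      return(finish(death))
    }
    t <- t + dur
    note(t, "lot_end", sprintf("lot%d", lot))
    scale3 <- lot >= 4
    bcr <- draw_cat(equation_key("bcr", lot))
    note(t, "bcr", sprintf("lot%d:%s", lot, bcr))
    set_bcr(if (scale3) as.integer(bcr) else collapse_bcr(bcr))
    add_line(lot, regimen, start, t, FALSE, lot == 1 && planned,
             if (scale3) bcr_levels()[2 * as.integer(bcr) - 1] else bcr)
    if (lot == 1) {
      bcr_first_val <- bcr
      got_asct <- FALSE
      if (planned && !(bcr %in% c("SD", "PD"))) {
        got_asct <- draw_flag("asct_receipt")
      }
      if (got_asct) {
        death <- draw_death(t)
        note(t, "asct_start")
        astart <- t
        adur <- draw_dur("dur_asct")
        if (death <= t + adur) {
          add_line(NA, "asct", astart, min(death, cap_t), TRUE, NA, NA)
          return(finish(death))
        }
        t <- t + adur
        note(t, "asct_end")
        abcr <- draw_cat(equation_key("bcr", asct = TRUE))
        note(t, "bcr", sprintf("asct:%s", abcr))
        x["post_asct"] <- 1
        set_bcr(collapse_bcr(abcr))
        bcr_first_val <- abcr
        add_line(NA, "asct", astart, t, TRUE, NA, abcr)
      }
      maint <- draw_flag("maintenance_receipt")
      if (maint) {
        ln_maint[1] <- TRUE
        note(t, "maintenance_start")
      }
    }
    if (lot < config$max_lot) {
      death <- draw_death(t)
      gapkey <- if (lot == 1 && maint) "dur_maintenance"
                else equation_key("tfi", lot, asct = x[["post_asct"]] > 0)
      gap <- draw_dur(gapkey)
      if (death <= t + gap) return(finish(death))
      t <- t + gap
    } else {
      death <- draw_death(t)
      return(finish(death))
    }
  }
  finish(draw_death(t))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d events, OS %.1f months (%s), %d line(s)\n",
              nrow(x), attr(x, "os_months"), attr(x, "terminal"),
              attr(x, "n_lots")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Simulate a cohort of patients
#'
#' Each patient is simulated under an independent RNG substream derived from
#' `config$seed` and the patient's position, so results are reproducible and
#' do not depend on iteration order.
#'
#' @param profiles data frame of fully observed diagnostic profiles
#'   (`age_dx, sex, ecog, iss`; a `patient_id` column is carried through)
#' @param coeffs a `model_coefficients` set
#' @param config a `simulation_config`
#' @return list of `trajectory` objects
#' @export
simulate_cohort <- function(profiles, coeffs, config = simulation_config()) {
  n <- nrow(profiles)
  if (is.null(n) || n == 0) return(list())
  ids <- profiles$patient_id %||% sprintf("S%05d", seq_len(n))
  attr(coeffs, "engine_cache") <- build_engine_cache(coeffs)
  age <- profiles$age_dx; sex <- profiles$sex
  ecog <- profiles$ecog; iss <- profiles$iss
  lapply(seq_len(n), function(i) {
    prof <- list(age_dx = age[i], sex = sex[i], ecog = ecog[i], iss = iss[i])
    tr <- with_seed(derive_seed(config$seed, 104729, i),
                    simulate_patient(prof, coeffs, config))
    attr(tr, "patient_id") <- ids[i]
    tr
  })
}

#' Summarize a simulated cohort
#'
#' @param trajectories list of `trajectory` objects
#' @return data frame with one row per patient: `patient_id`, `os_months`,
#'   `terminal`, `bcr_first` (best clinical response to LoT 1 for non-ASCT
#'   patients, to ASCT for ASCT patients), `n_lots`
#' @export
cohort_summary <- function(trajectories) {
  data.frame(
    patient_id = vapply(trajectories, function(t)
      attr(t, "patient_id") %||% NA_character_, character(1)),
    os_months = vapply(trajectories, attr, numeric(1), "os_months"),
    terminal = vapply(trajectories, attr, character(1), "terminal"),
    bcr_first = vapply(trajectories, attr, character(1), "bcr_first"),
    n_lots = vapply(trajectories, attr, integer(1), "n_lots"),
    stringsAsFactors = FALSE)
}

#' Convert simulated trajectories to registry treatment rows
#'
#' Lossless inverse of the simulation's bookkeeping: every chemotherapy line
#' and ASCT episode becomes one row in the registry `lines` layout.
#'
#' @param trajectories list of `trajectory` objects
#' @return data frame in the `lines` schema (without laboratory-change
#'   columns, which are registry measurements, not simulation outputs)
#' @export
trajectories_to_lines <- function(trajectories) {
  out <- lapply(trajectories, function(tr) {
    ln <- attr(tr, "lines")
    if (is.null(ln) || !nrow(ln)) return(NULL)
    ln$patient_id <- attr(tr, "patient_id") %||% NA_character_
    ln
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(patient_id = character(0), lot = integer(0),
                      regimen = character(0), start_time = numeric(0),
                      end_time = numeric(0), is_asct = logical(0),
                      asct_planned = logical(0), maintenance = logical(0),
                      bcr = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[c("patient_id", setdiff(names(res), "patient_id"))]
}
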