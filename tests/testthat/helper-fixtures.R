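# Shared fixtures, all built in code.

# hand-written miniature registry: 3 patients, mixed lines
tiny_registry <- function() {
  patients <- data.frame(
    patient_id = c("A", "B", "C"),
    age_dx = c(60, 72, 55),
    sex = c("male", "female", "male"),
    ecog = c("0", "2plus", NA),
    iss = c(1, NA, 3),
    paraprotein = c(30, 12, 50),
    kappa_lc = c(20, 100, 15),
    lambda_lc = c(18, 10, 40),
    death_time = c(40, NA, NA),
    censor_time = c(40, 60, 24),
    stringsAsFactors = FALSE)
  lines <- data.frame(
    patient_id = c("A", "A", "A", "B", "B", "C"),
    lot = c(1L, NA, 2L, 1L, 2L, 1L),
    regimen = c("VRd", "asct", "Rd", "Rd", "other", "VCd"),
    start_time = c(1, 7, 20, 2, 30, 0.5),
    end_time = c(6, 7.8, 30, 8, NA, NA),
    is_asct = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    asct_planned = c(TRUE, NA, NA, FALSE, NA, FALSE),
    maintenance = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    bcr = c("VGPR", "CR", "PR", "PR", NA, NA),
    dpp = c(-2.1, -3.0, -1.2, -1.0, -0.2, -2.5),
    dkappa = c(-1.9, -2.5, -1.0, -1.1, 0.1, -2.0),
    dlambda = c(-2.0, -2.8, -0.9, -0.8, -0.3, -1.8),
    stringsAsFactors = FALSE)
  registry_table(patients, lines)
}

# small synthetic registry cached per session (generation is deterministic)
small_registry <- local({
  cache <- NULL
  function(n = 600, seed = 402) {
    if (is.null(cache))
      cache <<- generate_registry(synth_config(n_patients = n, seed = seed))
    cache
  }
})

# an intercept-only survival equation for engine/primitive tests
plain_eq <- function(family, intercept, shape) {
  eq <- ground_truth_coefficients()$equations$os
  eq$family <- family
  eq$beta <- c("(Intercept)" = intercept)
  eq$term_names <- character(0)
  eq$ancillary <- list(shape = shape)
  eq
}
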