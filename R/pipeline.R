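# End-to-end orchestration: synth -> fit -> simulate -> validate, with a
# reproducibility manifest. The thin command-line wrapper in inst/cli calls
# straight into run_pipeline().

#' Run the modelling pipeline end to end
#'
#' Executes the requested stages in order on a run directory:
#' \describe{
#'   \item{synth}{generate a synthetic registry (`patients.csv`,
#'     `lines.csv`, `ground_truth.json`)}
#'   \item{fit}{multiply impute the registry and estimate all risk
#'     equations (`coefficients.json`)}
#'   \item{simulate}{simulate a cohort from the fitted coefficients
#'     (`trajectories.csv`)}
#'   \item{validate}{bootstrap out-of-sample validation (`monthly_p.csv`,
#'     `km_bands.csv`, `os_by_bcr.csv`)}
#' }
#' Every stage seeds its own stream from the master seed, and a
#' `manifest.json` (stages, parameters, seeds, package version) is written
#' alongside the outputs. Inputs on disk are never modified.
#'
#' @param config list with elements `out` (run directory), `seed`, `stages`
#'   (character subset of synth/fit/simulate/validate), and per-stage
#'   parameters: `n_patients`, `m`, `B`, `n_sim`
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(config) {
  out <- config$out %||% stop_("config$out (run directory) is required")
  seed <- config$seed %||% 1
  stages <- config$stages %||% c("synth", "fit", "simulate", "validate")
  bad <- setdiff(stages, c("synth", "fit", "simulate", "validate"))
  if (length(bad)) stop_("unknown stage(s): %s", paste(bad, collapse = ", "))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "myelosim",
                   version = as.character(utils::packageVersion("myelosim")),
                   seed = seed, stages = stages,
                   params = list(n_patients = config$n_patients %||% 4121,
                                 m = config$m %||% 10,
                                 B = config$B %||% 100,
                                 n_sim = config$n_sim %||% 10000))
  if ("synth" %in% stages) {
    sc <- synth_config(n_patients = config$n_patients %||% 4121,
                       seed = derive_seed(seed, 21))
    reg <- generate_registry(sc)
    write_registry(reg, out)
    write_coefficients(sc$ground_truth, file.path(out, "ground_truth.json"))
  }
  registry <- function() read_registry(config$registry %||% out)
  if ("fit" %in% stages) {
    reg <- drop_unended_lines(registry())
    spec <- imputation_spec(m = config$m %||% 10,
                            seed = derive_seed(seed, 22))
    mc <- estimate_all_equations(impute_registry(reg, spec))
    write_coefficients(mc, file.path(out, "coefficients.json"))
  }
  if ("simulate" %in% stages) {
    cpath <- config$coefficients %||% file.path(out, "coefficients.json")
    if (!file.exists(cpath))
      stop_("coefficients file not found: %s", cpath)
    mc <- read_coefficients(cpath)
    reg <- registry()
    spec <- imputation_spec(m = 2, seed = derive_seed(seed, 23))
    profiles <- impute_registry(reg, spec)[[1]]$patients
    n_sim <- config$n_sim %||% 10000
    idx <- with_seed(derive_seed(seed, 24),
                     sample.int(nrow(profiles), n_sim, replace = TRUE))
    trajs <- simulate_cohort(profiles[idx, ], mc,
                             simulation_config(n_sim,
                                               seed = derive_seed(seed, 25)))
    ev <- do.call(rbind, lapply(trajs, function(tr) {
      cbind(patient_id = attr(tr, "patient_id"), as.data.frame(tr))
    }))
    utils::write.csv(ev, file.path(out, "trajectories.csv"),
                     row.names = FALSE, na = "")
  }
  if ("validate" %in% stages) {
    reg <- registry()
    rep <- bootstrap_validate(
      reg, imputation_spec(m = config$m %||% 10,
                           seed = derive_seed(seed, 26)),
      B = config$B %||% 100, n_sim = config$n_sim %||% 10000,
      seed = derive_seed(seed, 27))
    utils::write.csv(rep$monthly[c("month", "c", "p")],
                     file.path(out, "monthly_p.csv"), row.names = FALSE)
    utils::write.csv(rep$monthly,
                     file.path(out, "km_bands.csv"), row.names = FALSE)
    ob <- rbind(cbind(cohort = "validation", rep$os_by_bcr_validation),
                cbind(cohort = "simulated", rep$os_by_bcr_simulated))
    utils::write.csv(ob, file.path(out, "os_by_bcr.csv"), row.names = FALSE)
    manifest$pct_nonsignificant <- rep$pct_nonsignificant
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
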