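# JSON serialization of a fitted (or ground-truth) coefficient set, so risk
# equations can be estimated once and reused across simulation runs.

#' Write a model-coefficients set to JSON
#'
#' @param coeffs a `model_coefficients` object
#' @param path output file
#' @return `path`, invisibly
#' @export
write_coefficients <- function(coeffs, path) {
  ser_eq <- function(eq) {
    anc <- eq$ancillary
    if (!is.null(anc$coef)) {
      anc$coef <- list(values = as.vector(anc$coef), nrow = nrow(anc$coef),
                       rownames = rownames(anc$coef),
                       colnames = colnames(anc$coef))
    }
    list(outcome = eq$outcome, state = eq$state, family = eq$family,
         term_names = eq$term_names,
         beta = as.list(stats::setNames(as.numeric(eq$beta),
                                        names(eq$beta))),
         ancillary = anc)
  }
  obj <- list(
    equations = lapply(coeffs$equations, ser_eq),
    curtailments = as.list(coeffs$curtailments),
    lot1_catalog = coeffs$config$lot1_catalog,
    lot2_catalog = coeffs$config$lot2_catalog,
    max_lot = coeffs$config$max_lot)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model-coefficients set from JSON
#'
#' @param path file written by [write_coefficients()]
#' @return a `model_coefficients` object
#' @export
read_coefficients <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  cfg <- framework_config(lot1_catalog = unlist(obj$lot1_catalog),
                          lot2_catalog = unlist(obj$lot2_catalog),
                          max_lot = obj$max_lot)
  des_eq <- function(e) {
    anc <- e$ancillary
    anc <- lapply(anc, function(v) if (is.list(v) && is.null(v$values))
      unlist(v) else v)
    if (!is.null(anc$coef)) {
      cf <- anc$coef
      anc$coef <- matrix(unlist(cf$values), nrow = cf$nrow, byrow = FALSE,
                         dimnames = list(unlist(cf$rownames),
                                         unlist(cf$colnames)))
    }
    if (!is.null(anc$cutpoints)) anc$cutpoints <- as.numeric(anc$cutpoints)
    if (!is.null(anc$knots)) anc$knots <- as.numeric(anc$knots)
    if (!is.null(anc$gamma)) anc$gamma <- as.numeric(anc$gamma)
    if (!is.null(anc$levels)) anc$levels <- as.character(unlist(anc$levels))
    beta <- unlist(e$beta)
    new_risk_equation(e$outcome, e$state, e$family, beta = beta,
                      term_names = as.character(unlist(e$term_names)),
                      ancillary = anc)
  }
  eqs <- lapply(obj$equations, des_eq)
  model_coefficients(eqs, unlist(obj$curtailments), cfg)
}
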