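#' Best-clinical-response scale
#'
#' The six-level ordinal best clinical response (BCR) scale used in myeloma,
#' ordered from best to worst: Complete Response, Very Good Partial Response,
#' Partial Response, Minimal Response, Stable Disease, Progressive Disease.
#'
#' @return character vector of the six level labels in order
#' @export
bcr_levels <- function() c("CR", "VGPR", "PR", "MR", "SD", "PD")

#' Collapse the 6-level BCR scale to 3 levels
#'
#' CR/VGPR -> 1, PR/MR -> 2, SD/PD -> 3. Missing responses propagate as
#' missing. The mapping is order-preserving.
#'
#' @param bcr character vector of 6-level labels (see [bcr_levels()]) or NA
#' @return integer vector in \{1, 2, 3\} with NA preserved
#' @export
collapse_bcr <- function(bcr) {
  if (length(bcr) == 0) return(integer(0))
  idx <- match(bcr, bcr_levels())
  bad <- !is.na(bcr) & is.na(idx)
  if (any(bad)) {
    stop_("unknown BCR label(s): %s; allowed labels are %s",
          paste(unique(bcr[bad]), collapse = ", "),
          paste(bcr_levels(), collapse = ", "))
  }
  as.integer(ceiling(idx / 2))
}

patient_columns <- function() {
  c("patient_id", "age_dx", "sex", "ecog", "iss", "paraprotein", "kappa_lc",
    "lambda_lc", "death_time", "censor_time")
}

line_columns <- function() {
  c("patient_id", "lot", "regimen", "start_time", "end_time", "is_asct",
    "asct_planned", "maintenance", "bcr", "dpp", "dkappa", "dlambda")
}

#' Construct a validated registry table
#'
#' The registry is a pair of tables: one diagnosis record per patient and one
#' record per treatment episode (chemotherapy line or autologous stem-cell
#' transplant). Times are continuous months since diagnosis. An ASCT episode
#' is a line row with `is_asct = TRUE` and `lot = NA`; chemotherapy rows carry
#' `lot` 1-9, strictly increasing within a patient. `dpp`, `dkappa` and
#' `dlambda` are within-line log-ratio changes in paraprotein and free light
#' chains, the laboratory signal from which missing best clinical response is
#' imputed.
#'
#' @param patients data frame with columns
#'   `patient_id, age_dx, sex ("male"/"female"), ecog ("0","1","2plus"),
#'   iss (1:3), paraprotein, kappa_lc, lambda_lc, death_time, censor_time`.
#'   Missing values are `NA`; a patient who died has
#'   `censor_time == death_time` (death ends follow-up).
#' @param lines data frame with columns
#'   `patient_id, lot, regimen, start_time, end_time, is_asct, asct_planned,
#'   maintenance, bcr, dpp, dkappa, dlambda`
#' @return object of class `registry_table`
#' @export
registry_table <- function(patients, lines) {
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  lines <- as.data.frame(lines, stringsAsFactors = FALSE)
  missing_p <- setdiff(patient_columns(), names(patients))
  if (length(missing_p)) stop_("patients table lacks column(s): %s",
                               paste(missing_p, collapse = ", "))
  missing_l <- setdiff(line_columns(), names(lines))
  if (length(missing_l)) stop_("lines table lacks column(s): %s",
                               paste(missing_l, collapse = ", "))
  patients <- patients[patient_columns()]
  lines <- lines[line_columns()]
  obj <- structure(list(patients = patients, lines = lines),
                   class = "registry_table")
  validate_registry(obj)
  obj
}

validate_registry <- function(x) {
  p <- x$patients; l <- x$lines
  chk_row <- function(ok, tbl, col, msg) {
    if (any(!ok, na.rm = FALSE)) {
      i <- which(!ok)[1]
      stop_("invalid %s row %d, column '%s': %s", tbl, i, col, msg)
    }
  }
  if (anyDuplicated(p$patient_id))
    stop_("duplicate patient_id in patients table")
  chk_row(is.na(p$age_dx) | (p$age_dx >= 18 & p$age_dx <= 100),
          "patients", "age_dx", "age at diagnosis must lie in [18, 100]")
  chk_row(is.na(p$sex) | p$sex %in% c("male", "female"),
          "patients", "sex", "must be 'male' or 'female'")
  chk_row(is.na(p$ecog) | p$ecog %in% c("0", "1", "2plus"),
          "patients", "ecog", "must be '0', '1' or '2plus'")
  chk_row(is.na(p$iss) | p$iss %in% 1:3, "patients", "iss",
          "must be 1, 2 or 3")
  chk_row(is.na(p$censor_time) | p$censor_time >= 0, "patients",
          "censor_time", "must be non-negative")
  chk_row(is.na(p$death_time) | p$death_time >= 0, "patients",
          "death_time", "must be non-negative")
  dead <- !is.na(p$death_time)
  chk_row(!dead | (p$censor_time == p$death_time), "patients", "death_time",
          "death supersedes censoring: censor_time must equal death_time")
  if (nrow(l)) {
    bad_ref <- !(l$patient_id %in% p$patient_id)
    if (any(bad_ref))
      stop_("lines reference unknown patient_id: %s",
            paste(unique(l$patient_id[bad_ref]), collapse = ", "))
    chk_row(is.na(l$bcr) | l$bcr %in% bcr_levels(), "lines", "bcr",
            sprintf("allowed labels are %s",
                    paste(bcr_levels(), collapse = ", ")))
    chk_row(l$start_time >= 0, "lines", "start_time", "must be non-negative")
    chk_row(is.na(l$end_time) | l$end_time > l$start_time, "lines",
            "end_time", "must exceed start_time when present")
    chk_row(l$is_asct | (!is.na(l$lot) & l$lot %in% 1:9), "lines", "lot",
            "chemotherapy rows need lot in 1..9")
    # per-patient ordering invariants on chemotherapy rows
    chem <- l[!l$is_asct, , drop = FALSE]
    if (nrow(chem)) {
      ord <- order(chem$patient_id, chem$lot)
      chem <- chem[ord, , drop = FALSE]
      same <- duplicated(chem$patient_id)
      if (any(same)) {
        prev <- c(NA, chem$lot[-nrow(chem)])
        if (any(same & chem$lot <= prev))
          stop_("lot numbers must be strictly increasing within a patient")
        prev_end <- c(NA, chem$end_time[-nrow(chem)])
        overlap <- same & !is.na(prev_end) & chem$start_time < prev_end
        if (any(overlap))
          stop_("treatment lines overlap for patient %s",
                chem$patient_id[which(overlap)[1]])
      }
    }
    # an ASCT row must follow the patient's LoT-1 line (when that line is
    # still present; the unended-line filter may have removed it)
    asct <- l[l$is_asct, , drop = FALSE]
    if (nrow(asct)) {
      l1 <- chem[chem$lot == 1, c("patient_id", "start_time")]
      m <- match(asct$patient_id, l1$patient_id)
      if (any(asct$start_time < l1$start_time[m], na.rm = TRUE))
        stop_("ASCT must follow induction (LoT 1) for patient %s",
              asct$patient_id[which(asct$start_time < l1$start_time[m])[1]])
    }
  }
  invisible(x)
}

#' @export
print.registry_table <- function(x, ...) {
  cat(sprintf("<registry_table> %d patients, %d treatment rows\n",
              nrow(x$patients), nrow(x$lines)))
  ndead <- sum(!is.na(x$patients$death_time))
  cat(sprintf("  deaths observed: %d (%.1f%%)\n", ndead,
              100 * ndead / max(1, nrow(x$patients))))
  invisible(x)
}

#' Number of patients in a registry
#' @param x a `registry_table`
#' @return integer
#' @export
n_patients <- function(x) nrow(x$patients)

#' Read a registry from CSV files
#'
#' Expects `patients.csv` and `lines.csv` under `path` (missing values as
#' empty fields). An optional schema configuration renames non-canonical
#' external column headers; it is a list with elements `patients` and/or
#' `lines`, each a named character vector `canonical = external`, or the path
#' to a YAML file with that structure.
#'
#' @param path directory containing the two CSV files
#' @param schema_config optional column mapping (list or YAML file path)
#' @return a validated [registry_table()]
#' @export
read_registry <- function(path, schema_config = NULL) {
  pf <- file.path(path, "patients.csv")
  lf <- file.path(path, "lines.csv")
  if (!file.exists(pf)) stop_("no patients.csv under %s", path)
  if (!file.exists(lf)) stop_("no lines.csv under %s", path)
  if (is.character(schema_config) && length(schema_config) == 1)
    schema_config <- yaml::read_yaml(schema_config)
  rename <- function(df, map) {
    if (is.null(map)) return(df)
    for (canon in names(map)) {
      j <- match(map[[canon]], names(df))
      if (!is.na(j)) names(df)[j] <- canon
    }
    df
  }
  p <- utils::read.csv(pf, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character"))
  l <- utils::read.csv(lf, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character"))
  p <- rename(p, schema_config$patients)
  l <- rename(l, schema_config$lines)
  if (nrow(p)) {
    p$ecog <- as.character(p$ecog)
    p$sex <- as.character(p$sex)
  }
  # ECOG 2/3/4 are merged at read time (low numbers in the high-morbidity
  # categories); external files may carry raw 0-4 codes.
  p$ecog[p$ecog %in% c("2", "3", "4")] <- "2plus"
  if (nrow(l)) {
    l$bcr <- as.character(l$bcr)
    l$bcr[!is.na(l$bcr) & l$bcr == ""] <- NA
    l$is_asct <- as.logical(l$is_asct)
    l$asct_planned <- as.logical(l$asct_planned)
    l$maintenance <- as.logical(l$maintenance)
  }
  p$ecog[!is.na(p$ecog) & p$ecog == ""] <- NA
  p$sex[!is.na(p$sex) & p$sex == ""] <- NA
  registry_table(p, l)
}

#' Write a registry to CSV files
#'
#' Inverse of [read_registry()]: writes `patients.csv` and `lines.csv` with
#' missing values as empty fields. Round-trips exactly.
#'
#' @param table a `registry_table`
#' @param path output directory (created if needed)
#' @return `path`, invisibly
#' @export
write_registry <- function(table, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(table$patients, file.path(path, "patients.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(table$lines, file.path(path, "lines.csv"),
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Drop treatment lines that must have ended but have no end date
#'
#' A line with a missing end date is dropped when the patient is known to
#' have moved on — they died, or a later treatment row starts after this
#' line's start. Lines with a missing end date and no later event are kept as
#' ongoing (their duration is censored at last follow-up). Keeping the
#' known-ended but unended-in-the-data lines would skew duration models with
#' spuriously long censored durations.
#'
#' The filter is idempotent and preserves referential integrity.
#'
#' @param table a `registry_table`
#' @return filtered `registry_table`
#' @export
drop_unended_lines <- function(table) {
  l <- table$lines
  if (!nrow(l)) return(table)
  p <- table$patients
  died <- !is.na(p$death_time)[match(l$patient_id, p$patient_id)]
  max_start <- stats::ave(l$start_time, l$patient_id, FUN = max)
  later_start <- l$start_time < max_start
  drop <- is.na(l$end_time) & (died | later_start)
  registry_table(p, l[!drop, , drop = FALSE])
}
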