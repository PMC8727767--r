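#' Load a patient cohort table
#'
#' Reads the per-patient clinical table from a comma-separated file, or the
#' packaged 32-patient cohort when `source = "fixture"`. The file must carry
#' one header row with the documented columns; missing values are empty cells.
#' The numeric age-at-injury covariate (`age_mid`) is derived from the age bin
#' midpoint (21.5, 32.5, 47.5, 62.5, 77.5 years): ages are published only in
#' bins, so the midpoint is the declared numeric approximation.
#'
#' @param source path to a CSV file, or `"fixture"` for the packaged cohort.
#' @return a validated [CohortTable-class].
#' @examples
#' cohort <- loadCohort()
#' nPatients(cohort)
#' @export
loadCohort <- function(source = "fixture") {
  if (identical(source, "fixture")) {
    path <- system.file("extdata", "tbi_cohort.csv", package = "sibsr")
    prov <- "fixture"
  } else {
    path <- source
    prov <- path
  }
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("parse error: cohort file has no data rows")
  need <- c("patient_id", "age_bin", "sex", "max_bsr", "max_gcs",
            "gose_discharge", "days_discharge", "gose_chronic", "days_chronic",
            "barbiturates", "propofol", "usable_sections", "total_sections")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("parse error: missing column(s) ", paste(miss, collapse = ", "))

  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(is.na(raw[[col]]) | raw[[col]] == ""))
    if (length(bad))
      stop(sprintf("parse error in row %d, column '%s': '%s'",
                   bad[1], col, raw[[col]][bad[1]]))
    v
  }
  r <- data.frame(
    patient_id = as.integer(num("patient_id")),
    age_bin = factor(raw$age_bin, levels = .AGE_BINS, ordered = TRUE),
    sex = raw$sex,
    max_bsr = num("max_bsr"),
    max_gcs = as.integer(num("max_gcs")),
    gose_discharge = as.integer(num("gose_discharge")),
    days_discharge = num("days_discharge"),
    gose_chronic = as.integer(num("gose_chronic")),
    days_chronic = num("days_chronic"),
    barbiturates = as.logical(raw$barbiturates),
    propofol = as.logical(raw$propofol),
    usable_sections = as.integer(num("usable_sections")),
    total_sections = as.integer(num("total_sections")),
    stringsAsFactors = FALSE)
  if (anyNA(r$age_bin))
    stop(sprintf("validation error in row %d, column 'age_bin': '%s'",
                 which(is.na(r$age_bin))[1], raw$age_bin[which(is.na(r$age_bin))[1]]))
  r$age_mid <- .AGE_MIDS[as.integer(r$age_bin)]
  r <- r[, c("patient_id", "age_bin", "age_mid", "sex", "max_bsr", "max_gcs",
             "gose_discharge", "days_discharge", "gose_chronic", "days_chronic",
             "barbiturates", "propofol", "usable_sections", "total_sections")]
  obj <- new("CohortTable", records = r, provenance = prov)
  validObject(obj)  # range checks double as the row validation errors
  obj
}

#' Write a cohort table to CSV
#'
#' Inverse of [loadCohort()]: writes the documented columns (without the
#' derived `age_mid`) with empty cells for missing values, so that a
#' write/read round trip reproduces the table.
#'
#' @param cohort a [CohortTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(is(cohort, "CohortTable"))
  r <- cohortData(cohort)
  r$age_bin <- as.character(r$age_bin)
  r <- r[, setdiff(names(r), "age_mid")]
  utils::write.csv(r, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Summarize a cohort
#'
#' Descriptive statistics of the cohort: mean and sample (n-1) standard
#' deviation of days to each outcome assessment, usable EEG sections and
#' percent of sections used, plus sex and medication counts. Days to the
#' chronic assessment are summarized over patients with a recorded assessment
#' day.
#'
#' @param cohort a [CohortTable-class].
#' @return a list with elements `days_discharge`, `days_chronic`,
#'   `usable_sections`, `percent_used` (each `c(mean, sd, n)`), and counts
#'   `sex`, `barbiturates`, `propofol`, `n_missing_chronic`.
#' @examples
#' summarizeCohort(loadCohort())$usable_sections
#' @export
summarizeCohort <- function(cohort) {
  stopifnot(is(cohort, "CohortTable"))
  r <- cohortData(cohort)
  if (nrow(r) == 0L) stop("empty cohort")
  msd <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_,
      n = length(x))
  }
  list(
    days_discharge = msd(r$days_discharge),
    days_chronic = msd(r$days_chronic),
    usable_sections = msd(r$usable_sections),
    percent_used = msd(100 * r$usable_sections / r$total_sections),
    sex = table(r$sex),
    barbiturates = sum(r$barbiturates),
    propofol = sum(r$propofol),
    n_missing_chronic = sum(is.na(r$gose_chronic)))
}

#' Medication indicators coded on the day of maximum BSR
#'
#' Returns the binary treatment variables used in the mediation analyses:
#' whether each patient received barbiturates / propofol on the same day as
#' their maximum BSR. The packaged cohort already encodes this same-day
#' coding; for cohorts carrying raw medication-day records, the flag is
#' derived by comparing the medication days against the day of maximum BSR
#' (columns `medication_days_<drug>` as comma-separated day indices and
#' `max_bsr_day`).
#'
#' @param cohort a [CohortTable-class].
#' @return data.frame with columns `patient_id`, `barbiturates`, `propofol`.
#'   Patients with missing medication data are dropped with a warning.
#' @export
codeMedication <- function(cohort) {
  stopifnot(is(cohort, "CohortTable"))
  r <- cohortData(cohort)
  out <- data.frame(patient_id = r$patient_id,
                    barbiturates = r$barbiturates, propofol = r$propofol)
  for (drug in c("barbiturates", "propofol")) {
    daycol <- paste0("medication_days_", drug)
    if (all(c(daycol, "max_bsr_day") %in% names(r))) {
      days <- strsplit(as.character(r[[daycol]]), ",")
      out[[drug]] <- mapply(function(d, b) as.numeric(b) %in% as.numeric(d),
                            days, r$max_bsr_day)
    }
  }
  drop <- is.na(out$barbiturates) | is.na(out$propofol)
  if (any(drop)) {
    warning("excluding ", sum(drop), " patient(s) with missing medication data")
    out <- out[!drop, ]
  }
  out
}
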