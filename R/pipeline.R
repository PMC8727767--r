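#' Constructor for a pipeline run configuration
#'
#' @param ... slot overrides, see [RunConfig-class].
#' @return a validated [RunConfig-class].
#' @export
runConfig <- function(...) {
  obj <- do.call(new, c(list("RunConfig"), list(...)))
  validObject(obj)
  obj
}

## Published age-free reference values the fixture run is compared against
## (model selection tables for the two outcomes). Used only for the pass/fail
## comparison report, never to produce results.
.REFERENCE_MODELS <- data.frame(
  outcome  = c("discharge", "discharge", "discharge", "chronic", "chronic",
               "chronic", "chronic"),
  terms    = c("maxBSR+maxGCS", "maxGCS", "(none)",
               "maxBSR+maxGCS+sex", "maxBSR+maxGCS", "maxGCS", "(none)"),
  logLik   = c(-5.366, -15.907, -21.170, -7.246, -8.980, -16.967, -20.794),
  AICc     = c(17.588, 36.227, 44.473, 24.093, 24.883, 38.378, 43.732),
  stringsAsFactors = FALSE)

.termKey <- function(fit) {
  if (length(fit@terms) == 0L) "(none)" else
    paste(sort(fit@terms), collapse = "+")
}

#' Reproduce the published fixture analysis
#'
#' Runs the complete statistical analysis on the packaged 32-patient cohort:
#' the 16-model logistic enumerations for discharge and chronic outcomes with
#' AICc, delta and Akaike weights; conditional model-averaged parameters;
#' outcome-vs-days-to-assessment correlations; the retained-vs-excluded
#' missing-data chi-squared tests; descriptive statistics; and a pass/fail
#' comparison of the age-free model rows against their published reference
#' values (rows involving the age covariate are approximate by construction,
#' since ages are recorded in bins).
#'
#' The excluded-patient outcome counts (`excludedDischarge`,
#' `excludedChronic`) are analysis inputs: the excluded patients are not part
#' of the packaged table.
#'
#' @param config a [RunConfig-class] (fixture mode).
#' @param excludedDischarge `c(above, below)` median-split counts among
#'   excluded patients at discharge.
#' @param excludedChronic same at the chronic timepoint.
#' @return a list bundle: `models` (per timepoint [ModelSet-class]),
#'   `modelTables`, `averaged` (per timepoint data.frame), `correlations`,
#'   `chiSquared`, `descriptives`, `comparison` (data.frame with `pass`
#'   column), `config`.
#' @export
reproducePaper <- function(config = runConfig(),
                           excludedDischarge = c(6, 2),
                           excludedChronic = c(4, 4)) {
  stopifnot(is(config, "RunConfig"))
  cohort <- loadCohort()
  r <- cohortData(cohort)

  models <- lapply(c(discharge = "discharge", chronic = "chronic"),
                   function(tp) enumerateModels(cohort, tp, config@windowDelta))
  averaged <- lapply(models, averageParameters)

  correlations <- list(
    discharge = pearsonR(r$gose_discharge, r$days_discharge),
    chronic = pearsonR(r$gose_chronic, r$days_chronic))

  yD <- medianSplit(r$gose_discharge, "discharge")
  yC <- medianSplit(r$gose_chronic, "chronic")
  chi <- list(
    discharge = chiSquared2x2(rbind(retained = c(sum(yD), sum(1 - yD)),
                                    excluded = excludedDischarge)),
    chronic = chiSquared2x2(rbind(retained = c(sum(yC, na.rm = TRUE),
                                               sum(1 - yC, na.rm = TRUE)),
                                  excluded = excludedChronic)))

  comparison <- .REFERENCE_MODELS
  comparison$logLik_computed <- NA_real_
  comparison$AICc_computed <- NA_real_
  for (i in seq_len(nrow(comparison))) {
    ms <- models[[comparison$outcome[i]]]
    keys <- vapply(ms@fits, .termKey, character(1))
    j <- match(comparison$terms[i], keys)
    comparison$logLik_computed[i] <- ms@fits[[j]]@logLik
    comparison$AICc_computed[i] <- ms@fits[[j]]@aicc
  }
  comparison$pass <- abs(comparison$logLik - comparison$logLik_computed) < 5e-3 &
    abs(comparison$AICc - comparison$AICc_computed) < 5e-3

  bundle <- list(models = models,
                 modelTables = lapply(models, modelTable),
                 averaged = averaged, correlations = correlations,
                 chiSquared = chi, descriptives = summarizeCohort(cohort),
                 comparison = comparison, config = config,
                 seed = config@seed)
  if (nzchar(config@outputDir)) .writeBundle(bundle, config)
  bundle
}

.writeBundle <- function(bundle, config) {
  dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
  for (tp in names(bundle$modelTables)) {
    utils::write.csv(bundle$modelTables[[tp]],
                     file.path(config@outputDir, paste0("models_", tp, ".csv")),
                     row.names = FALSE)
    utils::write.csv(bundle$averaged[[tp]],
                     file.path(config@outputDir, paste0("averaged_", tp, ".csv")),
                     row.names = FALSE)
  }
  run <- list(seed = config@seed, mode = config@mode,
              threshold_uv = config@thresholdUv,
              section_duration_s = config@sectionDurationS,
              spacing_h = config@spacingH, window_delta = config@windowDelta,
              n_sims = config@nSims)
  jsonlite::write_json(run, file.path(config@outputDir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Run the full pipeline end to end
#'
#' Chains every stage on a synthetic cohort: simulate GCS trajectories and
#' state-labeled EEG; select GCS-guided section timepoints; average
#' re-reference and band-pass each section; compute the BSR of each usable
#' section and the per-patient maximum; enumerate the logistic model set on
#' the resulting cohort; average parameters; and run the four medication
#' mediation analyses. Per-patient failures are isolated: a failing patient
#' is excluded (with a warning) and the pipeline continues.
#'
#' @param config a [RunConfig-class] in `"synthetic"` mode; `nPatients`, `fs`
#'   and `sectionDurationS` control the simulation scale.
#' @return a list bundle: `cohort` (with recomputed max BSR),
#'   `bsrTable` (per-section results), `truth`, `models`, `averaged`,
#'   `mediation` (list of [MediationResult-class]), `timings`, `seed`.
#' @export
runFullPipeline <- function(config = runConfig(mode = "synthetic",
                                               nPatients = 12, fs = 64,
                                               sectionDurationS = 60)) {
  stopifnot(is(config, "RunConfig"))
  if (config@mode != "synthetic")
    stop("runFullPipeline operates on synthetic cohorts; ",
         "use reproducePaper() for the packaged fixture")
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  params <- simParams(nPatients = config@nPatients, fs = config@fs,
                      sectionDurationS = config@sectionDurationS,
                      seed = config@seed)
  sim <- simulateCohort(params, signals = TRUE)
  timings["simulate"] <- tic() - t0

  t0 <- tic()
  rows <- list()
  for (i in seq_along(sim$sections)) {
    for (j in seq_along(sim$sections[[i]])) {
      res <- tryCatch({
        sec <- sim$sections[[i]][[j]]$section
        sec <- bandpassFilter(rereferenceAverage(sec),
                              highHz = min(45, 0.45 * config@fs))
        b <- computeBSR(sec, config@thresholdUv)
        data.frame(patient_id = i, section = j, bsr = bsr(b),
                   icc = b@icc, log10_kurtosis = b@log10Kurtosis,
                   gcs = sec@gcsAtExtraction, usable = sec@usable,
                   truth = sim$sections[[i]][[j]]$truth@suppressionFraction)
      }, error = function(e) {
        warning("patient ", i, " section ", j, " failed: ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  bsrTable <- do.call(rbind, rows)
  timings["bsr"] <- tic() - t0

  t0 <- tic()
  maxima <- maxBSRPerPatient(bsrTable)
  cohort <- sim$cohort
  idx <- match(as.integer(names(maxima)), cohortData(cohort)$patient_id)
  cohort@records$max_bsr[idx] <- as.numeric(maxima)
  cohort@records <- cohort@records[cohortData(cohort)$patient_id %in%
                                     as.integer(names(maxima)), ]
  models <- lapply(c(discharge = "discharge", chronic = "chronic"),
                   function(tp) enumerateModels(cohort, tp, config@windowDelta))
  averaged <- lapply(models, averageParameters)
  timings["models"] <- tic() - t0

  t0 <- tic()
  analyses <- list(c("barbiturates", "discharge"), c("barbiturates", "chronic"),
                   c("propofol", "discharge"), c("propofol", "chronic"))
  mediation <- lapply(analyses, function(a)
    tryCatch(runMediation(cohort, a[1], "maxBSR", a[2], nSims = config@nSims,
                          seed = .subSeed(config@seed, 99)),
             error = function(e) e))
  names(mediation) <- vapply(analyses, paste, character(1), collapse = "_")
  timings["mediation"] <- tic() - t0

  list(cohort = cohort, bsrTable = bsrTable, truth = sim$truth,
       models = models, averaged = averaged, mediation = mediation,
       timings = timings, seed = config@seed)
}
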