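#' @import methods
NULL

## Ordered age bins used in the clinical cohort and their numeric midpoints.
## Ages are recorded only as bins; the midpoint is the numeric "age at injury"
## covariate wherever age enters a model.
.AGE_BINS <- c("18-25", "25-40", "40-55", "55-70", "70-85")
.AGE_MIDS <- c(21.5, 32.5, 47.5, 62.5, 77.5)

#' CohortTable: one row per patient
#'
#' Container for the per-patient clinical table: demographics (age bin, sex),
#' maximum burst suppression ratio (BSR), maximum Glasgow Coma Scale (GCS)
#' score over the ICU stay, Glasgow Outcome Scale extended (GOSe) at hospital
#' discharge and at chronic (~6 month) follow-up with days to each assessment,
#' sedative medication indicators (barbiturates, propofol, coded on the day of
#' maximum BSR), and EEG section bookkeeping.
#'
#' @slot records data.frame with columns `patient_id`, `age_bin`, `age_mid`,
#'   `sex`, `max_bsr`, `max_gcs`, `gose_discharge`, `days_discharge`,
#'   `gose_chronic`, `days_chronic`, `barbiturates`, `propofol`,
#'   `usable_sections`, `total_sections`.
#' @slot provenance character scalar, e.g. `"fixture"` or `"synthetic"`.
#'
#' @seealso [loadCohort()], [summarizeCohort()], [simulateCohort()]
#' @export
setClass("CohortTable",
  representation(records = "data.frame", provenance = "character"))

setValidity("CohortTable", function(object) {
  r <- object@records
  msg <- character()
  need <- c("patient_id", "age_bin", "age_mid", "sex", "max_bsr", "max_gcs",
            "gose_discharge", "days_discharge", "gose_chronic", "days_chronic",
            "barbiturates", "propofol", "usable_sections", "total_sections")
  if (!all(need %in% names(r)))
    return(paste("missing columns:", paste(setdiff(need, names(r)), collapse = ", ")))
  if (anyDuplicated(r$patient_id)) msg <- c(msg, "patient_id must be unique")
  if (any(r$max_bsr < 0 | r$max_bsr > 1, na.rm = TRUE))
    msg <- c(msg, "max_bsr must lie in [0, 1]")
  if (any(r$max_gcs < 3 | r$max_gcs > 15, na.rm = TRUE))
    msg <- c(msg, "max_gcs must lie in [3, 15]")
  for (g in c("gose_discharge", "gose_chronic"))
    if (any(r[[g]] < 1 | r[[g]] > 8, na.rm = TRUE))
      msg <- c(msg, paste(g, "must lie in [1, 8] when present"))
  if (any(r$usable_sections > r$total_sections, na.rm = TRUE))
    msg <- c(msg, "usable_sections must not exceed total_sections")
  if (!all(r$sex %in% c("M", "F"))) msg <- c(msg, "sex must be 'M' or 'F'")
  ## a missing chronic GOSe implies a missing days-to-chronic; the converse
  ## does not hold (GOSe 1 = death is a valid score with no assessment day)
  if (any(is.na(r$gose_chronic) & !is.na(r$days_chronic)))
    msg <- c(msg, "days_chronic must be missing when gose_chronic is missing")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' EEGRecording: a multichannel EEG signal
#'
#' @slot signal numeric matrix, channels x samples, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels one label per channel (13 by default in this cohort).
#' @slot startTime recording start, hours since admission.
#' @slot badMask logical per-sample vector; `TRUE` marks samples excluded by
#'   external artifact review (this package never creates the mask itself).
#' @export
setClass("EEGRecording",
  representation(signal = "matrix", fs = "numeric", channelLabels = "character",
                 startTime = "numeric", badMask = "logical"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || object@fs <= 0) msg <- c(msg, "fs must be a positive scalar")
  if (nrow(object@signal) != length(object@channelLabels))
    msg <- c(msg, "one channel label per signal row required")
  if (length(object@badMask) != ncol(object@signal))
    msg <- c(msg, "badMask length must equal the number of samples")
  if (length(object@startTime) != 1L || object@startTime < 0)
    msg <- c(msg, "startTime must be a nonnegative scalar (hours)")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' EEGSection: a fixed-duration excerpt taken at a GCS-guided timepoint
#'
#' @slot t0 section start, hours since admission.
#' @slot durationS nominal duration in seconds (600 by default).
#' @slot gcsAtExtraction GCS score at the guiding assessment (NA if unknown).
#' @slot usable logical; `FALSE` when the bad-segment mask covers more than the
#'   allowed fraction of the section or extraction failed.
#' @export
setClass("EEGSection", contains = "EEGRecording",
  representation(t0 = "numeric", durationS = "numeric",
                 gcsAtExtraction = "numeric", usable = "logical"))

#' GCSSeries: repeated Glasgow Coma Scale assessments for one patient
#'
#' @slot timestamps hours since admission, strictly increasing.
#' @slot scores integer GCS scores in 3..15.
#' @export
setClass("GCSSeries",
  representation(timestamps = "numeric", scores = "integer"))

setValidity("GCSSeries", function(object) {
  msg <- character()
  if (length(object@timestamps) != length(object@scores))
    msg <- c(msg, "timestamps and scores must have equal length")
  if (is.unsorted(object@timestamps, strictly = TRUE))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (any(object@scores < 3L | object@scores > 15L))
    msg <- c(msg, "GCS scores must lie in [3, 15]")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' BSGroundTruth: the latent suppression state behind a synthetic section
#'
#' @slot statePath integer per-sample state (1 = suppression, 0 = burst).
#' @slot suppressionFraction realized fraction of suppression samples; the
#'   oracle against which downstream BSR estimates are checked.
#' @export
setClass("BSGroundTruth",
  representation(statePath = "integer", suppressionFraction = "numeric"))

setValidity("BSGroundTruth", function(object) {
  if (abs(mean(object@statePath) - object@suppressionFraction) > 1e-12)
    "suppressionFraction must equal mean(statePath)" else TRUE
})

#' SimParams: knobs of the synthetic burst-suppression EEG generator
#'
#' Defaults mirror the study conditions: 13 channels at 256 Hz, 10-minute
#' sections, a two-state alternating-renewal suppression process with
#' log-normal dwell times (~5 s mean per state), near-isoelectric suppression
#' noise (0.2 uV) well under the 1 uV rectified threshold, burst activity an
#' order of magnitude above it, rare per-channel state jitter so that
#' cross-channel agreement matches the near-perfect ICC reported clinically,
#' and a logistic outcome model on (max BSR, max GCS) with chronic-outcome
#' scale coefficients.
#'
#' @slot nPatients number of synthetic patients.
#' @slot fs sampling rate, Hz.
#' @slot sectionDurationS section length in seconds.
#' @slot burstDwellS mean burst dwell time, seconds.
#' @slot suppDwellS mean suppression dwell time, seconds (rescaled jointly with
#'   `burstDwellS` when a target suppression fraction is requested).
#' @slot dwellSdLog log-scale standard deviation of the log-normal dwell times.
#' @slot suppNoiseSd suppression-state noise standard deviation, uV.
#' @slot burstSd burst-state amplitude scale, uV.
#' @slot burstFloor minimum rectified burst amplitude, uV; keeps the labeled
#'   burst state identifiable sample-by-sample against the 1 uV threshold.
#' @slot jitterProb per-channel, per-sample probability of deviating from the
#'   common suppression state.
#' @slot outcomeCoef named numeric `(intercept, bsr, gcs)` of the logistic
#'   outcome model used to draw binary outcomes.
#' @slot seed integer seed; all generator randomness derives from it.
#' @export
setClass("SimParams",
  representation(nPatients = "numeric", fs = "numeric", sectionDurationS = "numeric",
                 burstDwellS = "numeric", suppDwellS = "numeric", dwellSdLog = "numeric",
                 suppNoiseSd = "numeric", burstSd = "numeric", burstFloor = "numeric",
                 jitterProb = "numeric", outcomeCoef = "numeric", seed = "numeric"),
  prototype(nPatients = 32, fs = 256, sectionDurationS = 600,
            burstDwellS = 5, suppDwellS = 5, dwellSdLog = 0.5,
            suppNoiseSd = 0.2, burstSd = 20, burstFloor = 5,
            jitterProb = 5e-4,
            outcomeCoef = c(intercept = -13, bsr = 8, gcs = 1), seed = 1))

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@burstDwellS <= 0 || object@suppDwellS <= 0)
    msg <- c(msg, "dwell times must be positive")
  if (object@jitterProb < 0 || object@jitterProb > 1)
    msg <- c(msg, "jitterProb must lie in [0, 1]")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (object@suppNoiseSd <= 0 || object@burstSd <= 0)
    msg <- c(msg, "noise scales must be positive")
  if (length(object@outcomeCoef) != 3L)
    msg <- c(msg, "outcomeCoef must have length 3 (intercept, bsr, gcs)")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' BSRResult: suppression statistics of one EEG section
#'
#' @slot bsr burst suppression ratio: fraction of unmasked samples whose
#'   cross-channel consensus rectified amplitude is below the threshold.
#' @slot thresholdUv rectified amplitude threshold, uV.
#' @slot perChannelFraction per-channel suppression fractions.
#' @slot consensus integer per-sample consensus series (1 = suppressed) over
#'   unmasked samples.
#' @slot log10Kurtosis base-10 log of the Pearson (non-excess) kurtosis of the
#'   pooled voltages; NA when undefined (flat signal).
#' @slot icc one-way random single-measure intraclass correlation of the
#'   binary suppression indicators across channels; NA when undefined.
#' @slot nSamplesUsed number of unmasked samples entering the proportion.
#' @slot meta list of computation metadata (ICC variant, kurtosis pooling).
#' @export
setClass("BSRResult",
  representation(bsr = "numeric", thresholdUv = "numeric",
                 perChannelFraction = "numeric", consensus = "integer",
                 log10Kurtosis = "numeric", icc = "numeric",
                 nSamplesUsed = "integer", meta = "list"))

setValidity("BSRResult", function(object) {
  msg <- character()
  if (abs(object@bsr - mean(object@consensus)) > 1e-12)
    msg <- c(msg, "bsr must equal the mean of the consensus series")
  if (any(object@perChannelFraction < 0 | object@perChannelFraction > 1))
    msg <- c(msg, "per-channel fractions must lie in [0, 1]")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' SensitivityReport: BSR threshold sensitivity diagnostics
#'
#' One entry per candidate rectified-amplitude threshold, each holding the
#' per-section BSR table with concurrent GCS, the Pearson correlation between
#' BSR and log10 kurtosis across sections, and the sections whose BSR exceeds
#' the "high" cutoff.
#'
#' @slot thresholds candidate thresholds in uV.
#' @slot highCutoff BSR value above which a section counts as high-BSR.
#' @slot results named list, one element per threshold, each a list with
#'   elements `table` (data.frame), `r` (correlation), `highSections`
#'   (data.frame subset).
#' @export
setClass("SensitivityReport",
  representation(thresholds = "numeric", highCutoff = "numeric", results = "list"))

setValidity("SensitivityReport", function(object) {
  if (length(object@results) != length(object@thresholds))
    "one result entry per threshold required" else TRUE
})

#' ModelFit: one fitted logistic regression model
#'
#' @slot terms predictor names (intercept always present, not listed).
#' @slot beta named coefficient vector in log-odds, intercept first.
#' @slot vcov coefficient covariance matrix (inverse observed information).
#' @slot logLik maximized log-likelihood.
#' @slot k number of estimated parameters (`length(terms) + 1`).
#' @slot n number of observations.
#' @slot aicc small-sample corrected Akaike information criterion.
#' @slot converged logical, IRLS convergence flag.
#' @slot degenerate logical; `TRUE` for boundary fits (single-class outcome or
#'   separated data with diverging coefficients).
#' @export
setClass("ModelFit",
  representation(terms = "character", beta = "numeric", vcov = "matrix",
                 logLik = "numeric", k = "integer", n = "integer",
                 aicc = "numeric", converged = "logical", degenerate = "logical"))

setValidity("ModelFit", function(object) {
  msg <- character()
  if (object@k != length(object@terms) + 1L)
    msg <- c(msg, "k must equal |terms| + 1")
  expected <- -2 * object@logLik + 2 * object@k +
    2 * object@k * (object@k + 1) / (object@n - object@k - 1)
  if (is.finite(expected) && is.finite(object@aicc) &&
      abs(object@aicc - expected) > 1e-8)
    msg <- c(msg, "aicc inconsistent with logLik, k, n")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' ModelSet: all candidate logistic models for one outcome
#'
#' Holds the 16 fits over subsets of {maxBSR, maxGCS, sex, age}, their AICc
#' differences from the leading model, and Akaike weights renormalized over
#' the selection window (delta <= `windowDelta`; models outside the window get
#' weight 0).
#'
#' @slot fits list of [ModelFit-class] objects, ordered by AICc.
#' @slot delta AICc difference to the leading model, per fit.
#' @slot weight Akaike weight per fit (0 outside the window).
#' @slot windowDelta selection window width in AICc units (5 by default).
#' @slot timepoint `"discharge"` or `"chronic"`.
#' @slot n observations used (complete cases for the timepoint).
#' @export
setClass("ModelSet",
  representation(fits = "list", delta = "numeric", weight = "numeric",
                 windowDelta = "numeric", timepoint = "character", n = "integer"))

setValidity("ModelSet", function(object) {
  msg <- character()
  if (length(object@fits) != length(object@delta) ||
      length(object@fits) != length(object@weight))
    return("fits, delta and weight must have equal length")
  if (sum(object@delta == 0) != 1L)
    msg <- c(msg, "exactly one fit must have delta = 0")
  inw <- object@delta <= object@windowDelta
  if (abs(sum(object@weight[inw]) - 1) > 1e-12)
    msg <- c(msg, "window weights must sum to 1")
  if (any(object@weight[!inw] != 0))
    msg <- c(msg, "weights outside the window must be 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' MediationResult: quasi-Bayesian causal mediation estimates
#'
#' Average causal mediation effects (ACME), average direct effects (ADE) and
#' the total effect on the probability (risk-difference) scale, with
#' Monte-Carlo percentile intervals and simulation p-values.
#'
#' @slot estimates named numeric: `acme0`, `acme1`, `ade0`, `ade1`, `acme`,
#'   `ade`, `total` (0/1 suffix = effect evaluated under control/treated).
#' @slot ci matrix with rows matching `estimates`, columns `lower`, `upper`.
#' @slot pvalues simulation p-values, same names as `estimates`.
#' @slot nSims number of Monte-Carlo parameter draws.
#' @slot seed integer seed used.
#' @slot spec list recording treatment, mediator, outcome, covariates, method
#'   and any separation flags.
#' @export
setClass("MediationResult",
  representation(estimates = "numeric", ci = "matrix", pvalues = "numeric",
                 nSims = "numeric", seed = "numeric", spec = "list"))

setValidity("MediationResult", function(object) {
  if (object@nSims < 100) "nSims must be at least 100" else TRUE
})

#' RunConfig: declarative configuration of a pipeline run
#'
#' All defaults mirror the analysis parameters: 1 uV rectified threshold,
#' 600 s sections, 24 h minimum spacing, AICc window of 5, 1000 mediation
#' simulations.
#'
#' @slot mode `"fixture"` or `"synthetic"`.
#' @slot thresholdUv rectified amplitude threshold, uV.
#' @slot sectionDurationS EEG section duration, seconds.
#' @slot spacingH minimum spacing between section timepoints, hours.
#' @slot windowDelta AICc selection window.
#' @slot nSims mediation Monte-Carlo draws.
#' @slot seed integer seed recorded in every artifact.
#' @slot nPatients synthetic-mode cohort size.
#' @slot fs synthetic-mode sampling rate, Hz.
#' @slot outputDir optional directory for delimited/JSON artifacts ("" = none).
#' @export
setClass("RunConfig",
  representation(mode = "character", thresholdUv = "numeric",
                 sectionDurationS = "numeric", spacingH = "numeric",
                 windowDelta = "numeric", nSims = "numeric", seed = "numeric",
                 nPatients = "numeric", fs = "numeric", outputDir = "character"),
  prototype(mode = "fixture", thresholdUv = 1, sectionDurationS = 600,
            spacingH = 24, windowDelta = 5, nSims = 1000, seed = 1,
            nPatients = 32, fs = 256, outputDir = ""))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (!object@mode %in% c("fixture", "synthetic"))
    msg <- c(msg, "mode must be 'fixture' or 'synthetic'")
  for (s in c("thresholdUv", "sectionDurationS", "spacingH", "windowDelta",
              "nSims", "nPatients", "fs"))
    if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be positive"))
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
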