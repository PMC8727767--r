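#' Accessors
#'
#' Small accessor generics for the package's S4 containers; use these rather
#' than reaching into slots.
#'
#' @param x an object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cohortData", function(x) standardGeneric("cohortData"))

#' @rdname accessors
#' @export
setGeneric("nPatients", function(x) standardGeneric("nPatients"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("badMask", function(x) standardGeneric("badMask"))

#' @rdname accessors
#' @export
setGeneric("bsr", function(x) standardGeneric("bsr"))

#' @rdname accessors
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' @rdname accessors
#' @export
setGeneric("modelTable", function(x) standardGeneric("modelTable"))

#' @rdname accessors
#' @export
setGeneric("effectEstimates", function(x) standardGeneric("effectEstimates"))

#' @rdname accessors
setMethod("cohortData", "CohortTable", function(x) x@records)

#' @rdname accessors
setMethod("nPatients", "CohortTable", function(x) nrow(x@records))

#' @rdname accessors
setMethod("provenance", "CohortTable", function(x) x@provenance)

#' @rdname accessors
setMethod("signalMatrix", "EEGRecording", function(x) x@signal)

#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(x) x@fs)

#' @rdname accessors
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)

#' @rdname accessors
setMethod("badMask", "EEGRecording", function(x) x@badMask)

#' @rdname accessors
setMethod("bsr", "BSRResult", function(x) x@bsr)

#' @rdname accessors
setMethod("modelWeights", "ModelSet", function(x) x@weight)

#' @rdname accessors
setMethod("effectEstimates", "MediationResult", function(x) x@estimates)

setMethod("show", "CohortTable", function(object) {
  r <- object@records
  cat(sprintf("CohortTable (%s): %d patients\n", object@provenance, nrow(r)))
  cat(sprintf("  max BSR: %.4f - %.4f; max GCS: %d - %d\n",
              min(r$max_bsr), max(r$max_bsr), min(r$max_gcs), max(r$max_gcs)))
  cat(sprintf("  chronic GOSe missing: %d\n", sum(is.na(r$gose_chronic))))
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("%s: %d channels x %d samples @ %g Hz (%.1f s), %d masked\n",
              class(object), nrow(object@signal), ncol(object@signal),
              object@fs, ncol(object@signal) / object@fs, sum(object@badMask)))
})

setMethod("show", "EEGSection", function(object) {
  callNextMethod()
  cat(sprintf("  t0 = %.2f h, GCS at extraction = %s, usable = %s\n",
              object@t0, format(object@gcsAtExtraction), object@usable))
})

setMethod("show", "BSRResult", function(object) {
  cat(sprintf("BSRResult: BSR = %.4f (threshold %g uV, %d samples)\n",
              object@bsr, object@thresholdUv, object@nSamplesUsed))
  cat(sprintf("  log10 kurtosis = %.3f, channel ICC = %.4f\n",
              object@log10Kurtosis, object@icc))
})

setMethod("show", "ModelSet", function(object) {
  cat(sprintf("ModelSet (%s outcome, n = %d): %d models, window delta <= %g\n",
              object@timepoint, object@n, length(object@fits), object@windowDelta))
  print(utils::head(modelTable(object), 5))
  cat("  ...\n")
})

setMethod("show", "MediationResult", function(object) {
  s <- object@spec
  cat(sprintf("MediationResult: %s -> %s -> %s (%s, %d sims)\n",
              s$treatment, s$mediator, s$outcome, s$method, object@nSims))
  tab <- data.frame(estimate = object@estimates,
                    lower = object@ci[, "lower"], upper = object@ci[, "upper"],
                    p = object@pvalues)
  print(round(tab, 4))
})
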