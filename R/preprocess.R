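#' Re-reference EEG to the common average
#'
#' Subtracts the instantaneous cross-channel mean from every channel, so the
#' cross-channel mean of the output is zero at every sample.
#'
#' @param rec an [EEGRecording-class] (or [EEGSection-class]).
#' @return an object of the same class with re-referenced signal.
#' @export
rereferenceAverage <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  if (nrow(rec@signal) < 2L)
    stop("average re-referencing requires at least 2 channels")
  out <- rec
  out@signal <- sweep(rec@signal, 2, colMeans(rec@signal))
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass (designed per band edge, i.e. a
#' 4th-order high-pass at `lowHz` cascaded with a 4th-order low-pass at
#' `highHz`) forward and backward (`filtfilt`), giving zero phase shift so
#' suppression-segment boundaries are not displaced in time. The default
#' 0.5-45 Hz band attenuates slow drift, muscle artifact and line noise.
#'
#' @param rec an [EEGRecording-class].
#' @param lowHz high-pass edge in Hz.
#' @param highHz low-pass edge in Hz; must be below Nyquist.
#' @param order Butterworth design order per band edge.
#' @return the filtered recording.
#' @export
bandpassFilter <- function(rec, lowHz = 0.5, highHz = 45, order = 4) {
  stopifnot(is(rec, "EEGRecording"))
  nyq <- rec@fs / 2
  if (!(lowHz > 0 && lowHz < highHz)) stop("need 0 < lowHz < highHz")
  if (highHz >= nyq) stop("highHz must be below the Nyquist frequency ", nyq)
  hp <- signal::butter(order, lowHz / nyq, type = "high")
  lp <- signal::butter(order, highHz / nyq, type = "low")
  out <- rec
  out@signal <- t(apply(rec@signal, 1, function(x)
    signal::filtfilt(lp, signal::filtfilt(hp, x))))
  out
}

#' GCS-guided selection of EEG section timepoints
#'
#' Implements the greedy selection used to target periods of minimal
#' responsiveness: assessments are sorted by ascending score (ties broken by
#' earlier timestamp); the lowest-scoring assessment seeds the selection; the
#' sorted list is then walked, adding every timestamp at least `minSpacingH`
#' hours from all timestamps already selected. Selected timestamps are
#' returned in chronological order and are pairwise at least `minSpacingH`
#' apart.
#'
#' @param gcs a [GCSSeries-class].
#' @param minSpacingH minimum spacing between selected timepoints, hours.
#' @return numeric vector of selected timestamps (hours), ascending.
#' @examples
#' g <- new("GCSSeries", timestamps = c(0, 10, 30, 60),
#'          scores = c(5L, 3L, 3L, 4L))
#' selectSectionTimes(g)  # 10 and 60
#' @export
selectSectionTimes <- function(gcs, minSpacingH = 24) {
  stopifnot(is(gcs, "GCSSeries"))
  if (length(gcs@timestamps) == 0L) stop("empty GCS series")
  ord <- order(gcs@scores, gcs@timestamps)
  ts <- gcs@timestamps[ord]
  selected <- ts[1]
  for (t in ts[-1])
    if (all(abs(t - selected) >= minSpacingH)) selected <- c(selected, t)
  sort(selected)
}

#' Extract fixed-duration EEG sections at selected timepoints
#'
#' Cuts one section per timestamp, starting at the timestamp (the assessment
#' anchors the section start; see `align`). Sections whose bad-segment mask
#' covers more than `maxBadFraction` of the samples are flagged unusable.
#' Timestamps whose section would fall outside the recording produce a
#' per-section error entry (attribute `"errors"`) rather than a failure.
#'
#' @param rec an [EEGRecording-class].
#' @param times section timepoints, hours since admission.
#' @param durationS section duration in seconds.
#' @param gcs optional numeric vector of GCS scores concurrent with `times`.
#' @param maxBadFraction maximum tolerated masked fraction before a section is
#'   flagged unusable.
#' @param align `"start"` (section begins at the timestamp) or `"center"`.
#' @return list of [EEGSection-class]; failed extractions are dropped and
#'   recorded in `attr(, "errors")` (data.frame of index, time, message).
#' @export
extractSections <- function(rec, times, durationS = 600, gcs = NULL,
                            maxBadFraction = 0.5, align = c("start", "center")) {
  stopifnot(is(rec, "EEGRecording"))
  align <- match.arg(align)
  if (is.null(gcs)) gcs <- rep(NA_real_, length(times))
  stopifnot(length(gcs) == length(times))
  nSamp <- ncol(rec@signal)
  len <- round(durationS * rec@fs)
  out <- list()
  errs <- data.frame(index = integer(), time = numeric(),
                     message = character(), stringsAsFactors = FALSE)
  for (j in seq_along(times)) {
    t0 <- times[j] - if (align == "center") durationS / 3600 / 2 else 0
    i0 <- round((t0 - rec@startTime) * 3600 * rec@fs) + 1L
    if (i0 < 1L || i0 + len - 1L > nSamp) {
      errs <- rbind(errs, data.frame(index = j, time = times[j],
                                     message = "section outside recording"))
      next
    }
    idx <- i0:(i0 + len - 1L)
    mask <- rec@badMask[idx]
    out[[length(out) + 1L]] <- new("EEGSection",
      signal = rec@signal[, idx, drop = FALSE], fs = rec@fs,
      channelLabels = rec@channelLabels, startTime = t0, badMask = mask,
      t0 = t0, durationS = durationS, gcsAtExtraction = as.numeric(gcs[j]),
      usable = mean(mask) <= maxBadFraction)
  }
  if (nrow(errs)) warning(nrow(errs), " section(s) could not be extracted")
  attr(out, "errors") <- errs
  out
}
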