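#' Binarize an EEG section at a rectified-amplitude threshold
#'
#' A sample is marked suppressed (1) when its rectified amplitude is strictly
#' below the threshold (`|x| < threshold`); samples exactly at the threshold
#' count as non-suppressed. Masked samples are dropped.
#'
#' @param section an [EEGSection-class] (or any [EEGRecording-class]).
#' @param thresholdUv rectified amplitude threshold in microvolts (> 0).
#' @return integer channels x samples matrix over unmasked samples.
#' @export
binarizeSuppression <- function(section, thresholdUv = 1) {
  stopifnot(is(section, "EEGRecording"))
  if (!is.numeric(thresholdUv) || thresholdUv <= 0)
    stop("thresholdUv must be positive")
  keep <- !section@badMask
  sig <- section@signal[, keep, drop = FALSE]
  b <- (abs(sig) < thresholdUv) + 0L
  storage.mode(b) <- "integer"
  b
}

#' Cross-channel consensus suppression series
#'
#' Per sample, the modal (majority) binary value across channels. With an odd
#' channel count (13 here) no ties arise; with an even count, ties resolve to
#' suppression (1).
#'
#' @param binary integer channels x samples binary matrix.
#' @return integer per-sample consensus vector.
#' @export
channelConsensus <- function(binary) {
  if (!is.matrix(binary) || nrow(binary) < 1L)
    stop("binary must be a matrix with at least 1 channel")
  as.integer(colMeans(binary) >= 0.5)
}

#' Pearson kurtosis of pooled voltages, log10-transformed
#'
#' Computes the non-excess (Pearson) kurtosis `m4 / m2^2` of the voltage
#' amplitudes pooled across channels over unmasked samples, and returns its
#' base-10 logarithm. A Gaussian signal gives log10(3) ~ 0.477; discontinuous
#' (burst-suppressed) signals give larger values, so the statistic scales
#' with the BSR, dropping again only for fully isoelectric data. A flat
#' (zero-variance) signal yields NA rather than an error.
#'
#' @param x an [EEGSection-class]/[EEGRecording-class], or a numeric vector.
#' @param perChannel logical; return one value per channel instead of the
#'   pooled statistic.
#' @return log10 kurtosis (scalar, or per-channel vector).
#' @export
logKurtosis <- function(x, perChannel = FALSE) {
  lk <- function(v) {
    m2 <- mean((v - mean(v))^2)
    if (!is.finite(m2) || m2 <= 0) return(NA_real_)
    log10(mean((v - mean(v))^4) / m2^2)
  }
  if (is(x, "EEGRecording")) {
    keep <- !x@badMask
    sig <- x@signal[, keep, drop = FALSE]
    if (ncol(sig) <= 3L) stop("need more than 3 usable samples")
    if (perChannel) return(apply(sig, 1, lk))
    lk(as.vector(sig))
  } else {
    if (length(x) <= 3L) stop("need more than 3 samples")
    lk(as.numeric(x))
  }
}

#' One-way random-effects intraclass correlation of binary indicators
#'
#' Single-measure ICC(1,1), treating samples as targets and channels as
#' raters: `(MSB - MSW) / (MSB + (k - 1) MSW)` from the one-way ANOVA of the
#' binary suppression indicators. Undefined (NA, with a warning) when the
#' between-sample variance is zero.
#'
#' @param binary integer channels x samples binary matrix (>= 2 channels,
#'   >= 2 samples).
#' @return ICC estimate in \[-1, 1\], or NA.
#' @export
channelICC <- function(binary) {
  if (!is.matrix(binary) || nrow(binary) < 2L || ncol(binary) < 2L)
    stop("need at least 2 channels and 2 samples")
  k <- nrow(binary); n <- ncol(binary)
  m <- colMeans(binary)
  grand <- mean(m)
  ssb <- k * sum((m - grand)^2)
  ssw <- sum(binary^2) - k * sum(m^2)  # binary: sum(x^2) = sum(x)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  if (msb <= 0) {
    warning("zero between-sample variance; ICC undefined")
    return(NA_real_)
  }
  (msb - msw) / (msb + (k - 1) * msw)
}

#' Burst suppression ratio of an EEG section
#'
#' The BSR is the proportion of the unmasked data whose rectified amplitude
#' lies below `thresholdUv` (1 uV by default), computed on the cross-channel
#' modal consensus series. Also reports the per-channel suppression fractions,
#' the pooled log10 kurtosis, and the one-way single-measure ICC of the binary
#' indicators across channels. The BSR is a continuous measure; no categorical
#' burst-suppression label is produced.
#'
#' @param section an [EEGSection-class] with at least one usable sample.
#' @param thresholdUv rectified amplitude threshold in microvolts.
#' @return a [BSRResult-class].
#' @examples
#' sim <- simulateBSEEG(simParams(sectionDurationS = 10, fs = 128), 0.6, seed = 2)
#' sec <- new("EEGSection", signal = sim$record@signal, fs = 128,
#'            channelLabels = channelLabels(sim$record), startTime = 0,
#'            badMask = badMask(sim$record), t0 = 0, durationS = 10,
#'            gcsAtExtraction = NA_real_, usable = TRUE)
#' bsr(computeBSR(sec))
#' @export
computeBSR <- function(section, thresholdUv = 1) {
  stopifnot(is(section, "EEGRecording"))
  if (sum(!section@badMask) == 0L)
    stop("no usable samples after masking")
  b <- binarizeSuppression(section, thresholdUv)
  cons <- channelConsensus(b)
  icc <- if (nrow(b) >= 2L && ncol(b) >= 2L)
    suppressWarnings(channelICC(b)) else NA_real_
  lk <- if (ncol(b) > 3L) logKurtosis(section) else NA_real_
  new("BSRResult", bsr = mean(cons), thresholdUv = thresholdUv,
      perChannelFraction = rowMeans(b), consensus = cons,
      log10Kurtosis = lk, icc = icc, nSamplesUsed = ncol(b),
      meta = list(iccVariant = "ICC(1,1) one-way random, single measure",
                  kurtosis = "Pearson (non-excess), pooled across channels"))
}

#' BSR threshold sensitivity analysis
#'
#' Recomputes the BSR of every section at each candidate threshold and
#' reports, per threshold, (1) the Pearson correlation between BSR and the
#' log10 kurtosis of the signal across sections, and (2) the sections whose
#' BSR exceeds `highCutoff` together with their concurrent GCS scores. These
#' are the two criteria used to select the working threshold: a sound
#' threshold yields high BSR only for sections at the floor of responsiveness
#' (GCS 3) and BSR values that scale with kurtosis.
#'
#' @param sections list of [EEGSection-class] with `gcsAtExtraction` set.
#' @param thresholds candidate thresholds in microvolts.
#' @param highCutoff BSR above which a section counts as high-BSR.
#' @return a [SensitivityReport-class].
#' @export
thresholdSensitivity <- function(sections, thresholds = c(1, 5, 10),
                                 highCutoff = 0.5) {
  stopifnot(length(sections) >= 2L)
  gcs <- vapply(sections, function(s) s@gcsAtExtraction, numeric(1))
  lk <- vapply(sections, logKurtosis, numeric(1))
  results <- lapply(thresholds, function(th) {
    vals <- vapply(sections, function(s) bsr(computeBSR(s, th)), numeric(1))
    tab <- data.frame(section = seq_along(sections), bsr = vals,
                      log10_kurtosis = lk, gcs = gcs)
    ok <- stats::complete.cases(tab[, c("bsr", "log10_kurtosis")])
    r <- if (sum(ok) >= 3 && stats::sd(vals[ok]) > 0 && stats::sd(lk[ok]) > 0)
      stats::cor(vals[ok], lk[ok]) else NA_real_
    list(table = tab, r = r, highSections = tab[tab$bsr > highCutoff, ])
  })
  names(results) <- paste0(thresholds, "uV")
  new("SensitivityReport", thresholds = thresholds, highCutoff = highCutoff,
      results = results)
}

#' Per-patient maximum BSR
#'
#' The greatest depth of burst suppression per patient: the maximum BSR over
#' that patient's usable sections. Patients with no usable section are
#' excluded with a warning.
#'
#' @param bsrTable data.frame with columns `patient_id`, `bsr`, and
#'   optionally `usable` (default all usable).
#' @return named numeric vector of per-patient maxima.
#' @export
maxBSRPerPatient <- function(bsrTable) {
  stopifnot(all(c("patient_id", "bsr") %in% names(bsrTable)))
  if (is.null(bsrTable$usable)) bsrTable$usable <- TRUE
  all_ids <- unique(bsrTable$patient_id)
  use <- bsrTable[bsrTable$usable, ]
  dropped <- setdiff(all_ids, unique(use$patient_id))
  if (length(dropped))
    warning("excluding patient(s) with no usable section: ",
            paste(dropped, collapse = ", "))
  tapply(use$bsr, factor(use$patient_id, levels = setdiff(all_ids, dropped)),
         max)
}
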