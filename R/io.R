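#' Write / read multichannel EEG as a delimited matrix with a JSON sidecar
#'
#' The on-disk form is plain text: a channels-x-samples numeric CSV (one row
#' per channel, no header) plus `<path>.json` holding the sampling rate,
#' channel labels, start time and the indices of masked samples.
#'
#' @param rec an [EEGRecording-class].
#' @param path output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
writeEEGMatrix <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  utils::write.table(rec@signal, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(fs = rec@fs, channel_labels = rec@channelLabels,
               start_time_h = rec@startTime,
               bad_sample_indices = which(rec@badMask))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeEEGMatrix
#' @export
readEEGMatrix <- function(path) {
  sig <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(sig) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mask <- rep(FALSE, ncol(sig))
  mask[as.integer(meta$bad_sample_indices)] <- TRUE
  new("EEGRecording", signal = sig, fs = as.numeric(meta$fs),
      channelLabels = as.character(meta$channel_labels),
      startTime = as.numeric(meta$start_time_h), badMask = mask)
}

#' Read a GCS assessment series from two-column delimited text
#'
#' Expects columns `hours` and `score` (header optional when the first field
#' is non-numeric).
#'
#' @param path input path.
#' @return a [GCSSeries-class].
#' @export
readGCS <- function(path) {
  first <- utils::read.table(path, sep = "", nrows = 1,
                             stringsAsFactors = FALSE)
  header <- is.na(suppressWarnings(as.numeric(first[[1]])))
  tab <- utils::read.table(path, sep = "", header = header)
  new("GCSSeries", timestamps = as.numeric(tab[[1]]),
      scores = as.integer(tab[[2]]))
}

#' @rdname readGCS
#' @param gcs a [GCSSeries-class] to write.
#' @export
writeGCS <- function(gcs, path) {
  stopifnot(is(gcs, "GCSSeries"))
  utils::write.table(data.frame(hours = gcs@timestamps, score = gcs@scores),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
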