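#' Construct a multichannel EEG recording
#'
#' Container for one subject's continuous EEG: a channels x samples matrix in
#' microvolts, its sampling rate, ordered channel names, and an optional
#' per-sample artifact mask (`TRUE` = contaminated).
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel_names Character vector, one name per row of `data`.
#' @param artifact_mask Optional logical vector of length `ncol(data)`.
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(19 * 512), 19), 256, eeg_montage())
#' rec
eeg_recording <- function(data, sampling_rate, channel_names,
                          artifact_mask = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  if (length(channel_names) != nrow(data))
    stop("rows(data) must equal length(channel_names)")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0)
    stop("`sampling_rate` must be a positive scalar")
  if (!is.null(artifact_mask)) {
    if (!is.logical(artifact_mask) || length(artifact_mask) != ncol(data))
      stop("`artifact_mask` must be logical with one entry per sample")
  }
  structure(
    list(data = data, sampling_rate = sampling_rate,
         channel_names = as.character(channel_names),
         artifact_mask = artifact_mask),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  if (!is.null(x$artifact_mask))
    cat(sprintf("  artifact mask: %.1f%% of samples flagged\n",
                100 * mean(x$artifact_mask)))
  invisible(x)
}

#' Write a recording as tab-separated text
#'
#' Plain-text dialect used as the package's interchange format: a header row of
#' channel names followed by one row per sample (samples x channels,
#' tab-separated). The artifact mask, when present, is stored as an extra
#' `.mask` column of 0/1.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_txt <- function(rec, path) {
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_names
  if (!is.null(rec$artifact_mask)) df[[".mask"]] <- as.integer(rec$artifact_mask)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recording written by [write_recording_txt()]
#'
#' @param path File path.
#' @param sampling_rate Sampling rate in Hz (the text dialect does not embed
#'   it; cohort manifests carry it alongside the file name).
#' @return An [eeg_recording()].
#' @export
read_recording_txt <- function(path, sampling_rate) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  mask <- NULL
  if (".mask" %in% names(df)) {
    mask <- as.logical(df[[".mask"]])
    df[[".mask"]] <- NULL
  }
  m <- t(as.matrix(df))
  dimnames(m) <- NULL
  eeg_recording(m, sampling_rate, names(df), mask)
}
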