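#' Continuous multi-channel EEG recording
#'
#' Lightweight container for a continuous recording: a channels x samples
#' matrix in microvolts, the sampling rate, the time of the first sample, and
#' an event table (cue onsets and pulse times in absolute ms).
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param ch_names Character vector of channel names (rows of `data`).
#' @param t0 Time of the first sample in ms (default 0).
#' @param events Tibble of events; columns are format-free but the pipeline
#'   uses `cue_onset` and `p1`..`p4` (absolute ms).
#' @return An object of class `eeg_raw`.
#' @export
eeg_raw <- function(data, fs, ch_names = rownames(data), t0 = 0,
                    events = tibble::tibble()) {
  if (!is.matrix(data)) stop_bad_arg("data must be a channels x samples matrix")
  if (fs <= 0) stop_bad_arg("fs must be positive")
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(nrow(data)))
  stopifnot(length(ch_names) == nrow(data))
  rownames(data) <- ch_names
  structure(
    list(data = data, fs = fs, ch_names = ch_names, t0 = t0, events = events),
    class = "eeg_raw"
  )
}

#' @export
print.eeg_raw <- function(x, ...) {
  cat(sprintf(
    "<eeg_raw> %d channels x %d samples @ %g Hz, t = [%g, %g] ms, %d events\n",
    nrow(x$data), ncol(x$data), x$fs, x$t0,
    x$t0 + (ncol(x$data) - 1) * 1000 / x$fs, nrow(x$events)
  ))
  invisible(x)
}

# sample times of a continuous recording, in ms
raw_times <- function(raw) raw$t0 + (seq_len(ncol(raw$data)) - 1) * 1000 / raw$fs

#' Epoched EEG data
#'
#' Trials x channels x samples array with a shared time axis (ms, t = 0 at
#' the pre-cue onset) and per-trial metadata (condition labels and pulse
#' times) in a tibble.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param times Time axis in ms, length `dim(data)[3]`.
#' @param fs Sampling rate in Hz.
#' @param ch_names Channel names, length `dim(data)[2]`.
#' @param info Tibble with one row per trial (condition labels, `p1`..`p4`).
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, times, fs, ch_names, info = NULL) {
  stopifnot(length(dim(data)) == 3, length(times) == dim(data)[3],
            length(ch_names) == dim(data)[2])
  if (is.null(info)) info <- tibble::tibble(.rows = dim(data)[1])
  stopifnot(nrow(info) == dim(data)[1])
  structure(
    list(data = data, times = times, fs = fs, ch_names = ch_names, info = info),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, t = [%g, %g] ms\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
    min(x$times), max(x$times)
  ))
  invisible(x)
}

#' Subset epochs by trial
#'
#' @param epochs An [eeg_epochs()] object.
#' @param which Logical or integer index into trials.
#' @return An [eeg_epochs()] object with the selected trials.
#' @export
epochs_subset <- function(epochs, which) {
  if (is.logical(which)) which <- which(which)
  eeg_epochs(
    epochs$data[which, , , drop = FALSE], epochs$times, epochs$fs,
    epochs$ch_names, epochs$info[which, , drop = FALSE]
  )
}
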