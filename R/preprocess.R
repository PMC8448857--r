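#' Interpolate TMS pulse artifacts
#'
#' Replaces the signal from 1 ms before to 13 ms after each pulse (closed
#' interval on the native sample grid) with shape-preserving piecewise cubic
#' Hermite (Fritsch-Carlson) interpolation anchored on the surrounding clean
#' samples, per channel. Samples outside the replacement windows are returned
#' bit-identical. The same operation is applied to sham data with "virtual"
#' pulse times, so any processing footprint is condition-symmetric.
#'
#' @param raw An [eeg_raw()] recording.
#' @param pulse_times Pulse onset times in absolute ms, sorted; windows must
#'   be non-overlapping (guaranteed upstream by >= 20 ms inter-pulse gaps)
#'   and fall inside the recording.
#' @param pre,post Window extent around each pulse in ms (defaults -1/+13).
#' @param n_anchor Number of clean samples used on each side of a window as
#'   interpolation anchors (default 20).
#' @return An [eeg_raw()] with artifact windows replaced.
#' @export
interpolate_artifacts <- function(raw, pulse_times, pre = 1, post = 13,
                                  n_anchor = 20) {
  if (length(pulse_times) == 0) return(raw)
  pulse_times <- sort(pulse_times)
  times <- raw_times(raw)
  eps <- 1e-9
  dat <- raw$data
  for (tp in pulse_times) {
    win <- which(times >= tp - pre - eps & times <= tp + post + eps)
    if (length(win) == 0) next
    if (win[1] - n_anchor < 1 || win[length(win)] + n_anchor > length(times)) {
      stop_bad_arg("interpolation window extends beyond the recording")
    }
    anchors <- c(win[1] - (n_anchor:1), win[length(win)] + (1:n_anchor))
    for (ch in seq_len(nrow(dat))) {
      dat[ch, win] <- pracma::pchip(times[anchors], dat[ch, anchors], times[win])
    }
  }
  out <- raw
  out$data <- dat
  out
}

#' Downsample a recording with anti-alias filtering
#'
#' Zero-phase low-pass filtering (4th-order Butterworth applied forward and
#' backward, i.e. an effective 8th-order zero-phase response) with cutoff at
#' 0.4 x the target rate, followed by decimation. Event times, stored in ms,
#' are unaffected.
#'
#' @param raw An [eeg_raw()] recording.
#' @param target_fs Target sampling rate in Hz; must divide `raw$fs`.
#' @return An [eeg_raw()] at `target_fs`.
#' @export
downsample <- function(raw, target_fs) {
  factor <- raw$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stop_bad_arg("target_fs must divide the sampling rate (integer decimation)")
  }
  factor <- round(factor)
  dat <- raw$data
  wc <- 0.4 * target_fs / (raw$fs / 2)
  if (wc < 1) {
    bf <- signal::butter(4, wc)
    for (ch in seq_len(nrow(dat))) {
      dat[ch, ] <- signal::filtfilt(bf, dat[ch, ])
    }
  }
  if (factor > 1) {
    dat <- dat[, seq(1, ncol(dat), by = factor), drop = FALSE]
  }
  eeg_raw(dat, target_fs, raw$ch_names, t0 = raw$t0, events = raw$events)
}

#' Segment a recording into epochs
#'
#' Cuts per-trial slices around each pre-cue onset with the half-open sample
#' convention `[start, end)` and re-references time so that the cue onset is
#' t = 0. Cues whose window falls outside the recording are skipped with a
#' warning.
#'
#' @param raw An [eeg_raw()] recording.
#' @param cue_onsets Pre-cue onset times in absolute ms.
#' @param window Epoch window in ms relative to cue onset (default
#'   `c(-300, 900)`).
#' @param info Optional tibble of per-trial metadata (one row per cue);
#'   rows of skipped cues are dropped.
#' @return An [eeg_epochs()] object.
#' @export
epoch <- function(raw, cue_onsets, window = c(-300, 900), info = NULL) {
  n_samp <- round((window[2] - window[1]) * raw$fs / 1000)
  times_rel <- window[1] + (seq_len(n_samp) - 1) * 1000 / raw$fs
  n_total <- ncol(raw$data)
  start_idx <- round((cue_onsets + window[1] - raw$t0) * raw$fs / 1000) + 1
  ok <- start_idx >= 1 & (start_idx + n_samp - 1) <= n_total
  if (any(!ok)) {
    warn(sprintf("%d trial(s) outside the recording were skipped", sum(!ok)))
  }
  keep <- which(ok)
  dat <- array(0, c(length(keep), nrow(raw$data), n_samp))
  for (k in seq_along(keep)) {
    dat[k, , ] <- raw$data[, start_idx[keep[k]] + seq_len(n_samp) - 1]
  }
  if (!is.null(info)) info <- info[keep, , drop = FALSE]
  eeg_epochs(dat, times_rel, raw$fs, raw$ch_names, info)
}

#' Preprocess a simulated or recorded session
#'
#' The full preprocessing chain applied identically to active and sham data:
#' pulse-artifact interpolation (using each trial's pulse times, including
#' the sham trials' virtual pulse times), downsampling to `target_fs`, and
#' epoching around every pre-cue onset. Requires the `events` table of the
#' recording to contain `cue_onset` and `p1`..`p4` columns in absolute ms.
#'
#' @param raw An [eeg_raw()] session (e.g. from [simulate_session()]).
#' @param target_fs Analysis sampling rate (default 100 Hz).
#' @param window Epoch window in ms (default `c(-300, 900)`).
#' @return An [eeg_epochs()] whose `info` carries the session's per-trial
#'   event metadata with pulse times re-expressed relative to cue onset.
#' @export
preprocess_session <- function(raw, target_fs = 100, window = c(-300, 900)) {
  ev <- raw$events
  stopifnot(all(c("cue_onset", "p1", "p2", "p3", "p4") %in% names(ev)))
  pulses <- sort(unlist(ev[, c("p1", "p2", "p3", "p4")], use.names = FALSE))
  clean <- interpolate_artifacts(raw, pulses)
  ds <- downsample(clean, target_fs)
  info <- ev
  for (p in c("p1", "p2", "p3", "p4")) info[[p]] <- ev[[p]] - ev$cue_onset
  epoch(ds, ev$cue_onset, window = window, info = info)
}
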