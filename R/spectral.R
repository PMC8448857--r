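#' Morlet wavelet bank
#'
#' A bank of complex Morlet wavelets with a fixed number of cycles. The
#' Gaussian envelope SD is `sigma_t = cycles / (2 * pi * f)`, giving the
#' closed-form resolutions
#' `FWHM_time(f) = cycles * sqrt(2 * log(2)) / (pi * f)` seconds and
#' `FWHM_freq(f) = 2 * sqrt(2 * log(2)) * f / cycles` Hz — at 10 Hz with five
#' cycles, 0.19 s and 4.71 Hz.
#'
#' @param freqs Center frequencies in Hz (default 3-50 in 1 Hz steps).
#' @param cycles Number of cycles per wavelet (default 5).
#' @return A tibble of class `wavelet_bank` with columns `freq`, `cycles`,
#'   `sigma_t` (s), `fwhm_time` (s), `fwhm_freq` (Hz).
#' @examples
#' wavelet_bank(freqs = 10)
#' @export
wavelet_bank <- function(freqs = 3:50, cycles = 5) {
  stopifnot(all(freqs > 0), cycles > 0)
  out <- tibble::tibble(
    freq = as.numeric(freqs),
    cycles = cycles,
    sigma_t = cycles / (2 * pi * freqs),
    fwhm_time = cycles * sqrt(2 * log(2)) / (pi * freqs),
    fwhm_freq = 2 * sqrt(2 * log(2)) * freqs / cycles
  )
  class(out) <- c("wavelet_bank", class(out))
  out
}

#' Sampled complex Morlet kernel
#'
#' The kernel is normalized to unit gain at its center frequency: convolving
#' it with a unit-amplitude sinusoid at `freq` yields modulus 1, so wavelet
#' amplitudes are interpretable in the input's units (microvolts).
#'
#' @param freq Center frequency in Hz.
#' @param cycles Number of cycles.
#' @param fs Sampling rate in Hz.
#' @param support Half-support in units of the envelope SD (default 3.5).
#' @return Complex vector of odd length with attributes `t` (time axis in s)
#'   and `half_support` (s).
#' @export
morlet_kernel <- function(freq, cycles = 5, fs, support = 3.5) {
  sigma <- cycles / (2 * pi * freq)
  h <- ceiling(support * sigma * fs) / fs
  t <- seq(-h, h, by = 1 / fs)
  env <- exp(-t^2 / (2 * sigma^2))
  carrier <- exp(2i * pi * freq * t)
  # zero-mean correction: the truncated kernel would otherwise pass DC
  k0 <- sum(env * carrier) / sum(env)
  k <- env * (carrier - k0) / (sum(env) / 2)
  attr(k, "t") <- t
  attr(k, "half_support") <- h
  k
}

# FWHM of a sampled non-negative profile by linear interpolation at half max
measure_fwhm <- function(x, axis) {
  x <- as.numeric(x)
  half <- max(x) / 2
  above <- which(x >= half)
  i1 <- above[1]
  i2 <- above[length(above)]
  lo <- if (i1 == 1) axis[1] else {
    approx(x[c(i1 - 1, i1)], axis[c(i1 - 1, i1)], xout = half)$y
  }
  hi <- if (i2 == length(x)) axis[length(x)] else {
    approx(x[c(i2, i2 + 1)], axis[c(i2, i2 + 1)], xout = half)$y
  }
  hi - lo
}

#' Measure a Morlet kernel's temporal and spectral FWHM
#'
#' Numerically measures the full width at half maximum of the sampled
#' kernel's temporal amplitude envelope and of its Fourier amplitude profile;
#' a direct check of the closed forms reported by [wavelet_bank()].
#'
#' @inheritParams morlet_kernel
#' @return Named numeric vector `c(fwhm_time = ..., fwhm_freq = ...)` in
#'   seconds and Hz.
#' @export
morlet_fwhm <- function(freq, cycles = 5, fs = 1000) {
  k <- morlet_kernel(freq, cycles, fs, support = 6)
  t <- attr(k, "t")
  fw_t <- measure_fwhm(Mod(k), t)
  nfft <- nextn(length(k) * 16, 2)
  spec <- Mod(fft(c(k, rep(0, nfft - length(k)))))
  fax <- (seq_len(nfft) - 1) * fs / nfft
  keep <- fax <= fs / 2
  fw_f <- measure_fwhm(spec[keep], fax[keep])
  c(fwhm_time = fw_t, fwhm_freq = fw_f)
}

#' Time-frequency map container
#'
#' @param data Array: `trials x channels x freqs x times` (complex,
#'   single-trial) or `channels x freqs x times` (real, amplitude or ITPC).
#' @param freqs Frequency axis in Hz.
#' @param times Time axis in ms.
#' @param ch_names Channel names.
#' @param quantity One of "complex", "evoked_amplitude", "itpc".
#' @param valid Logical freqs x times matrix; FALSE where the coefficient
#'   lies within half a wavelet support of an epoch edge.
#' @return An object of class `tf_map`.
#' @export
tf_map <- function(data, freqs, times, ch_names, quantity, valid) {
  structure(
    list(data = data, freqs = freqs, times = times, ch_names = ch_names,
         quantity = quantity, valid = valid),
    class = "tf_map"
  )
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf(
    "<tf_map> %s: %s; %d freqs (%g-%g Hz) x %d times (%g-%g ms)\n",
    x$quantity, paste(dim(x$data), collapse = " x "),
    length(x$freqs), min(x$freqs), max(x$freqs),
    length(x$times), min(x$times), max(x$times)
  ))
  invisible(x)
}

#' Morlet wavelet transform of epoched data
#'
#' Convolves every trial and channel with the complex Morlet kernels of the
#' bank (unit gain at each center frequency; phase convention: the
#' coefficient's angle equals the instantaneous phase of a cosine at the
#' center frequency). No padding is used; coefficients within half the
#' wavelet's FWHM duration of an epoch edge (where an appreciable part of the
#' kernel mass falls outside the data) are flagged invalid and should be
#' excluded from statistics.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param bank A [wavelet_bank()].
#' @return A complex [tf_map()] with `trials x channels x freqs x times`
#'   data.
#' @export
wavelet_transform <- function(epochs, bank) {
  fs <- epochs$fs
  if (any(bank$freq > fs / 2)) {
    stop_bad_arg("bank contains frequencies above Nyquist")
  }
  d <- dim(epochs$data)
  n_trial <- d[1]; n_chan <- d[2]; n_time <- d[3]
  # signals as columns of a (time x trial*channel) matrix
  x <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n_time)
  out <- array(
    0i, c(n_trial, n_chan, nrow(bank), n_time),
    dimnames = list(NULL, epochs$ch_names, NULL, NULL)
  )
  valid <- matrix(FALSE, nrow(bank), n_time)
  dur <- (n_time - 1) / fs
  for (j in seq_len(nrow(bank))) {
    k <- morlet_kernel(bank$freq[j], bank$cycles[j], fs)
    L <- length(k)
    if (attr(k, "half_support") * 2 > dur) {
      stop_bad_arg("epoch shorter than the longest wavelet support")
    }
    npad <- nextn(n_time + L - 1, 2)
    kf <- fft(c(k, rep(0i, npad - L)))
    xf <- mvfft(rbind(x, matrix(0, npad - n_time, ncol(x))))
    y <- mvfft(xf * kf, inverse = TRUE) / npad
    y <- y[(L - 1) / 2 + seq_len(n_time), , drop = FALSE] # center alignment
    out[, , j, ] <- array(t(y), c(n_trial, n_chan, n_time))
    edge <- bank$fwhm_time[j] / 2 * 1000 # ms
    valid[j, ] <- epochs$times >= epochs$times[1] + edge &
      epochs$times <= epochs$times[n_time] - edge
  }
  tf_map(out, bank$freq, epochs$times, epochs$ch_names, "complex", valid)
}

#' Evoked oscillation amplitude
#'
#' The phase-locked amplitude signature: trials are averaged in the time
#' domain first, and the Morlet amplitude (square root of power, i.e. the
#' modulus) of the average waveform is returned. Activity that is not
#' phase-locked across trials cancels in the average.
#'
#' @inheritParams wavelet_transform
#' @return A real [tf_map()] with `channels x freqs x times` data, quantity
#'   `"evoked_amplitude"`.
#' @export
evoked_amplitude <- function(epochs, bank) {
  if (dim(epochs$data)[1] < 1) stop_bad_arg("no trials to average")
  avg <- apply(epochs$data, c(2, 3), mean)
  ep1 <- eeg_epochs(
    array(avg, c(1, dim(avg))), epochs$times, epochs$fs, epochs$ch_names
  )
  tf <- wavelet_transform(ep1, bank)
  amp <- Mod(tf$data[1, , , , drop = TRUE])
  amp <- array(amp, dim(tf$data)[2:4])
  dimnames(amp) <- list(epochs$ch_names, NULL, NULL)
  tf_map(amp, tf$freqs, tf$times, tf$ch_names, "evoked_amplitude", tf$valid)
}

#' Inter-trial phase coherence
#'
#' ITPC (phase-locking value) at each channel, frequency and time point: the
#' modulus of the across-trial mean unit phasor, `|sum(exp(1i * theta)) / N|`
#' where `theta` are the single-trial phases. 0 means random phases, 1
#' perfect phase alignment; amplitude does not enter.
#'
#' @param trial_tf A complex [tf_map()] from [wavelet_transform()] with at
#'   least 2 trials.
#' @return A real [tf_map()] with `channels x freqs x times` data, quantity
#'   `"itpc"`.
#' @export
itpc <- function(trial_tf) {
  stopifnot(inherits(trial_tf, "tf_map"), trial_tf$quantity == "complex")
  n <- dim(trial_tf$data)[1]
  if (n < 2) stop_bad_arg("ITPC requires at least 2 trials")
  phasor <- trial_tf$data / Mod(trial_tf$data)
  phasor[!is.finite(phasor)] <- 0i # zero-amplitude coefficients carry no phase
  val <- Mod(apply(phasor, c(2, 3, 4), mean))
  dimnames(val) <- list(trial_tf$ch_names, NULL, NULL)
  tf_map(val, trial_tf$freqs, trial_tf$times, trial_tf$ch_names, "itpc",
         trial_tf$valid)
}

#' Pre-TMS alpha phase per trial
#'
#' Extracts each trial's oscillatory phase at a given frequency and time -
#' by default 10 Hz at t = -95 ms, i.e. 200 ms before the first pulse (105
#' ms). Phasors are averaged across the requested channels before taking the
#' angle, wrapped to `[-pi, pi)`.
#'
#' @param trial_tf A complex [tf_map()].
#' @param f Frequency in Hz (default 10).
#' @param t Time in ms (default -95); must lie in the valid (non-edge)
#'   region. Times between samples are handled by linear interpolation of
#'   the unit phasors of the two bracketing samples.
#' @param channels Channels to average (default `c("O2", "PO4")`,
#'   falling back to all channels if absent).
#' @return Numeric vector of per-trial phases in radians.
#' @export
pre_tms_phase <- function(trial_tf, f = 10, t = -95,
                          channels = c("O2", "PO4")) {
  fi <- which.min(abs(trial_tf$freqs - f))
  lo <- max(which(trial_tf$times <= t + 1e-9))
  hi <- min(which(trial_tf$times >= t - 1e-9))
  if (!trial_tf$valid[fi, lo] || !trial_tf$valid[fi, hi]) {
    stop_bad_arg("requested time lies in the edge-flagged region")
  }
  chans <- intersect(channels, trial_tf$ch_names)
  if (length(chans) == 0) chans <- trial_tf$ch_names
  ci <- match(chans, trial_tf$ch_names)
  unit <- function(z) {
    u <- z / Mod(z)
    u[!is.finite(u)] <- 0i
    u
  }
  p_lo <- unit(trial_tf$data[, ci, fi, lo, drop = FALSE])
  p_hi <- unit(trial_tf$data[, ci, fi, hi, drop = FALSE])
  w <- if (hi == lo) 0 else {
    (t - trial_tf$times[lo]) / (trial_tf$times[hi] - trial_tf$times[lo])
  }
  phasor <- (1 - w) * p_lo + w * p_hi
  wrap_phase(Arg(apply(phasor, 1, sum)))
}

# Welch power spectral density: Hann-windowed segments, averaged
welch_psd <- function(x, fs, seg_s = 2, overlap = 0.5) {
  nseg <- round(seg_s * fs)
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  scale <- fs * sum(w^2)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s + seq_len(nseg) - 1]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(fft(seg))^2 / scale
  }
  psd <- acc / length(starts)
  keep <- seq_len(floor(nseg / 2) + 1)
  tibble::tibble(freq = (keep - 1) * fs / nseg, power = psd[keep])
}

#' Estimate the individual alpha frequency
#'
#' IAF is the frequency of the maximum peak of the Welch periodogram of a
#' resting-state recording, restricted to the alpha search band (7-13 Hz).
#' Welch parameters: 2 s Hann segments with 50% overlap (0.5 Hz resolution).
#' If the band argmax is not a local maximum (no alpha peak), the boundary
#' argmax is returned with a warning.
#'
#' @param rest An [eeg_raw()] resting recording (first channel is used),
#'   at least 10 s long.
#' @param band Search band in Hz (default `c(7, 13)`).
#' @param seg_s Welch segment length in seconds (default 2).
#' @return IAF in Hz (numeric scalar).
#' @export
estimate_iaf <- function(rest, band = c(7, 13), seg_s = 2) {
  x <- rest$data[1, ]
  if (length(x) / rest$fs < 10) stop_bad_arg("rest recording shorter than 10 s")
  psd <- welch_psd(x, rest$fs, seg_s = seg_s)
  inband <- which(psd$freq >= band[1] & psd$freq <= band[2])
  i <- inband[which.max(psd$power[inband])]
  is_peak <- i > 1 && i < nrow(psd) &&
    psd$power[i] >= psd$power[i - 1] && psd$power[i] >= psd$power[i + 1] &&
    i != inband[1] && i != inband[length(inband)]
  if (!is_peak) {
    warn("no local alpha peak in the search band; returning boundary argmax")
  }
  psd$freq[i]
}
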