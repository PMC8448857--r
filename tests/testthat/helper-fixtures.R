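# Fixture builders shared across test files. Everything is generated in code;
# seeds are fixed so failures are reproducible.

# epochs holding identical copies of an arbitrary channels x samples matrix
epochs_from_matrix <- function(m, n_trials, fs, t_start = -300) {
  times <- t_start + (seq_len(ncol(m)) - 1) * 1000 / fs
  dat <- array(0, c(n_trials, nrow(m), ncol(m)))
  for (k in seq_len(n_trials)) dat[k, , ] <- m
  eeg_epochs(dat, times, fs, paste0("ch", seq_len(nrow(m))))
}

# epochs of single-channel cosines with given amplitudes/freqs/phases per trial
cosine_epochs <- function(n_trials, freq = 10, amp = 1, phase = 0, fs = 100,
                          t_start = -300, n_samp = 120) {
  amp <- rep_len(amp, n_trials)
  phase <- rep_len(phase, n_trials)
  times <- t_start + (seq_len(n_samp) - 1) * 1000 / fs
  dat <- array(0, c(n_trials, 1, n_samp))
  for (k in seq_len(n_trials)) {
    dat[k, 1, ] <- amp[k] * cos(2 * pi * freq * times / 1000 + phase[k])
  }
  eeg_epochs(dat, times, fs, "ch1")
}

# a small rhythmic-active schedule without the full blocked design
flat_schedule <- function(n_trials, rhythmicity = "rhythmic",
                          stimulation = "active", seed = 1) {
  dplyr::bind_cols(
    tibble::tibble(
      rhythmicity = rhythmicity, stimulation = stimulation,
      target_side = "left"
    ),
    pulse_trains(n_trials, rhythmicity, seed = seed)
  )
}

# Rayleigh test p-value (large-sample approximation) for phase uniformity
rayleigh_p <- function(phases) {
  n <- length(phases)
  rbar <- Mod(mean(exp(1i * phases)))
  z <- n * rbar^2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}

# cached simulated session + epochs used by several spectral/stats tests
shared_entrained_epochs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mod <- oscillator_model(iaf = 10, kappa = 1, alpha_amp = 10,
                              noise_amp = 5)
      sched <- flat_schedule(150)
      raw <- simulate_session(mod, sched, montage_1020(8), fs = 1000,
                              seed = 501)
      cache <<- preprocess_session(raw)
    }
    cache
  }
})
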