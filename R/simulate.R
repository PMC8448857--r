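#' Phase-resetting alpha oscillator model
#'
#' Parameters of the generative model used for synthetic TMS-EEG data: a
#' single cortical alpha oscillator at the participant's intrinsic alpha
#' frequency (IAF), partially phase-reset by each active TMS pulse, riding on
#' 1/f background noise, projected to the scalp through a right-occipital
#' gain map, with an additive spike artifact on active pulses.
#'
#' The reset law is `phase <- phase + kappa * wrap(reset_phase - phase)`:
#' `kappa = 0` leaves the phase untouched, `kappa = 1` is a hard reset to
#' `reset_phase`. `kappa_mod` makes the effective reset strength depend on
#' the pre-burst phase, `kappa * (1 + kappa_mod * cos(phase_pre -
#' reset_phase))` clipped to `[0, 1]`, which induces the phase-bin dependence
#' probed by the sinusoidal regression analysis.
#'
#' @param iaf Intrinsic alpha frequency in Hz, in `[7, 13]`.
#' @param alpha_amp Oscillation amplitude in microvolts.
#' @param freq_jitter Trial-to-trial SD of the oscillator frequency in Hz
#'   (default 0.5). Alpha frequency fluctuates around the IAF from moment to
#'   moment; without this the phase would advance deterministically and the
#'   pre-pulse phase would fix the phase at every later time, making
#'   phase-decorrelation (and hence entrainment re-alignment) unobservable.
#' @param kappa Per-pulse phase-reset fraction in `[0, 1]`.
#' @param reset_phase Target phase of the reset, radians.
#' @param kappa_mod Depth in `[0, 1]` of the pre-phase modulation of `kappa`
#'   (default 0: reset strength independent of ongoing phase).
#' @param noise_exponent Spectral slope of the background noise (power ~
#'   1/f^exponent).
#' @param noise_amp Background noise RMS amplitude in microvolts.
#' @param artifact_amp Peak amplitude of the pulse spike artifact, microvolts.
#' @param artifact_duration Artifact duration in ms, in `[4, 10]`.
#' @return An object of class `oscillator_model` (a validated list).
#' @examples
#' oscillator_model(iaf = 10.5, kappa = 0.8)
#' @export
oscillator_model <- function(iaf = 10, alpha_amp = 10, freq_jitter = 0.5,
                             kappa = 0.8, reset_phase = 0, kappa_mod = 0,
                             noise_exponent = 1, noise_amp = 10,
                             artifact_amp = 500, artifact_duration = 8) {
  if (iaf < 7 || iaf > 13) stop_bad_arg("iaf must lie in [7, 13] Hz")
  if (kappa < 0 || kappa > 1) stop_bad_arg("kappa must lie in [0, 1]")
  if (artifact_duration < 4 || artifact_duration > 10) {
    stop_bad_arg("artifact_duration must lie in [4, 10] ms")
  }
  if (alpha_amp < 0 || noise_amp < 0 || artifact_amp < 0) {
    stop_bad_arg("amplitudes must be non-negative")
  }
  if (freq_jitter < 0) stop_bad_arg("freq_jitter must be non-negative")
  structure(
    list(
      iaf = iaf, alpha_amp = alpha_amp, freq_jitter = freq_jitter,
      kappa = kappa, reset_phase = reset_phase, kappa_mod = kappa_mod,
      noise_exponent = noise_exponent, noise_amp = noise_amp,
      artifact_amp = artifact_amp, artifact_duration = artifact_duration
    ),
    class = "oscillator_model"
  )
}

#' @export
print.oscillator_model <- function(x, ...) {
  cat(sprintf(
    "<oscillator_model> iaf %.2f Hz, alpha %.3g uV, kappa %.2f (mod %.2f), noise 1/f^%.2g x %.3g uV\n",
    x$iaf, x$alpha_amp, x$kappa, x$kappa_mod, x$noise_exponent, x$noise_amp
  ))
  invisible(x)
}

# 1/f^exponent noise with the stated RMS, by spectral shaping of white noise
noise_1f <- function(n, fs, exponent, amp) {
  if (amp == 0) return(numeric(n))
  nf <- nextn(n, 2)
  freqs <- c(1, seq_len(nf / 2), rev(seq_len(nf / 2 - 1))) * fs / nf
  shape <- freqs^(-exponent / 2)
  spec <- shape * (rnorm(nf) + 1i * rnorm(nf))
  x <- Re(fft(spec, inverse = TRUE))[seq_len(n)]
  amp * (x - mean(x)) / sd(x)
}

# damped-oscillation spike artifact starting at time tp
artifact_waveform <- function(times, tp, amp, duration) {
  dt <- times - tp
  idx <- dt >= 0 & dt <= duration
  a <- numeric(length(times))
  a[idx] <- amp * exp(-dt[idx] / (duration / 4)) * sin(2 * pi * 0.25 * dt[idx])
  a
}

# core generator: one trial, channels x samples, at native rate
simulate_trial_matrix <- function(model, pulses, active, gain, fs, times, seed) {
  with_seed(seed, {
    n <- length(times)
    phi0 <- runif(1, 0, 2 * pi)
    # the oscillator runs at the IAF perturbed by slow trial-to-trial drift
    f_trial <- model$iaf + rnorm(1, 0, model$freq_jitter)
    w <- 2 * pi * f_trial / 1000
    # effective reset strength set by the phase 200 ms before the first pulse
    phi_pre <- phi0 + w * ((pulses[1] - 200) - times[1])
    kappa_eff <- model$kappa *
      (1 + model$kappa_mod * cos(phi_pre - model$reset_phase))
    kappa_eff <- min(max(kappa_eff, 0), 1)
    phi <- phi0 + w * (times - times[1])
    if (active && kappa_eff > 0) {
      for (tp in pulses) {
        idx <- times >= tp
        if (!any(idx)) next
        i1 <- which(idx)[1]
        phi_at <- phi[i1] - w * (times[i1] - tp)
        phi[idx] <- phi[idx] + kappa_eff * wrap_phase(model$reset_phase - phi_at)
      }
    }
    osc <- model$alpha_amp * cos(phi)
    art <- numeric(n)
    if (active && model$artifact_amp > 0) {
      for (tp in pulses) {
        amp <- model$artifact_amp * runif(1, 0.8, 1.2) * sample(c(-1, 1), 1)
        art <- art + artifact_waveform(times, tp, amp, model$artifact_duration)
      }
    }
    out <- matrix(0, length(gain), n)
    for (ch in seq_along(gain)) {
      out[ch, ] <- gain[ch] * osc + (0.3 + 0.7 * gain[ch]) * art +
        noise_1f(n, fs, model$noise_exponent, model$noise_amp)
    }
    out
  })
}

#' Simulate one raw trial
#'
#' Generates a single trial of raw multi-channel EEG at the native sampling
#' rate: the alpha oscillator (with partial phase resets at active pulses and
#' uniform random initial phase), 1/f background noise per channel, and - on
#' active trials only - a spike artifact at each pulse. Sham trials receive
#' neither reset nor artifact. The oscillator is projected onto channels with
#' a right-occipital gain map peaking at O2/PO4.
#'
#' @param model An [oscillator_model()].
#' @param trial One-row tibble with `stimulation` ("active"/"sham") and pulse
#'   onsets `p1`..`p4` in ms (e.g. one row of [make_trial_schedule()]).
#' @param montage Electrode layout tibble from [montage_1020()].
#' @param fs Sampling rate in Hz, at least 1000 (artifacts must be
#'   resolvable).
#' @param t_span Time span in ms; must cover `[-300, 900]` and the pulse
#'   train.
#' @param seed Integer seed; output is a deterministic function of all
#'   arguments.
#' @return An [eeg_raw()] with `t0 = t_span[1]` and the pulse times in
#'   `events`.
#' @export
simulate_epoch <- function(model, trial, montage = montage_1020(8), fs = 2500,
                           t_span = c(-300, 900), seed) {
  if (fs < 1000) stop_bad_arg("fs must be at least 1000 Hz")
  if (t_span[1] > -300 || t_span[2] < 900) {
    stop_bad_arg("t_span must cover [-300, 900] ms")
  }
  pulses <- as.numeric(trial[1, c("p1", "p2", "p3", "p4")])
  if (any(pulses < t_span[1]) || any(pulses > t_span[2])) {
    stop_bad_arg("t_span does not cover the pulse train")
  }
  times <- seq(t_span[1], t_span[2], by = 1000 / fs)
  gain <- occipital_gain(montage)
  dat <- simulate_trial_matrix(
    model, pulses, trial$stimulation[1] == "active", gain, fs, times, seed
  )
  eeg_raw(dat, fs, montage$channel, t0 = t_span[1],
          events = tibble::tibble(
            cue_onset = 0, p1 = pulses[1], p2 = pulses[2],
            p3 = pulses[3], p4 = pulses[4]
          ))
}

#' Simulate a full recording session
#'
#' Concatenates all trials of a schedule into one continuous raw recording
#' (each trial occupies `[t_span[1], t_span[2])` ms around its pre-cue
#' onset), so that the downstream artifact interpolation, downsampling and
#' epoching stages operate exactly as they would on a recorded session.
#'
#' @inheritParams simulate_epoch
#' @param schedule Trial schedule tibble from [make_trial_schedule()].
#' @return An [eeg_raw()]; `events` holds one row per trial with the absolute
#'   `cue_onset` and pulse times `p1`..`p4`, plus the schedule's condition
#'   labels.
#' @export
simulate_session <- function(model, schedule, montage = montage_1020(8),
                             fs = 2500, t_span = c(-300, 900), seed) {
  if (fs < 1000) stop_bad_arg("fs must be at least 1000 Hz")
  n_trial <- nrow(schedule)
  span <- t_span[2] - t_span[1]
  n_per <- round(span * fs / 1000) # half-open trial slots
  seeds <- child_seeds(seed, n_trial)
  gain <- occipital_gain(montage)
  times_rel <- t_span[1] + (seq_len(n_per) - 1) * 1000 / fs
  dat <- matrix(0, nrow(montage), n_per * n_trial)
  cue_abs <- numeric(n_trial)
  for (k in seq_len(n_trial)) {
    pulses <- as.numeric(schedule[k, c("p1", "p2", "p3", "p4")])
    m <- simulate_trial_matrix(
      model, pulses, schedule$stimulation[k] == "active", gain, fs,
      times_rel, seeds[k]
    )
    dat[, (k - 1) * n_per + seq_len(n_per)] <- m
    cue_abs[k] <- (k - 1) * span - t_span[1]
  }
  events <- dplyr::bind_cols(
    tibble::tibble(cue_onset = cue_abs),
    dplyr::select(schedule, -dplyr::any_of(c("p1", "p2", "p3", "p4"))),
    tibble::tibble(
      p1 = cue_abs + schedule$p1, p2 = cue_abs + schedule$p2,
      p3 = cue_abs + schedule$p3, p4 = cue_abs + schedule$p4
    )
  )
  eeg_raw(dat, fs, montage$channel, t0 = 0, events = events)
}

#' Simulate an eyes-closed resting-state recording
#'
#' A stationary alpha oscillator at the model IAF (no pulses, no resets) over
#' 1/f background noise, single channel; used to exercise the IAF estimator.
#'
#' @param model An [oscillator_model()].
#' @param duration Duration in seconds, at least 10.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @return An [eeg_raw()] with one channel.
#' @export
simulate_rest <- function(model, duration = 120, fs = 500, seed) {
  if (duration < 10) stop_bad_arg("duration must be at least 10 s")
  with_seed(seed, {
    n <- round(duration * fs)
    t <- (seq_len(n) - 1) / fs
    phi0 <- runif(1, 0, 2 * pi)
    x <- model$alpha_amp * cos(2 * pi * model$iaf * t + phi0) +
      noise_1f(n, fs, model$noise_exponent, model$noise_amp)
    eeg_raw(matrix(x, 1), fs, "Oz", t0 = 0)
  })
}

#' Simulate an unbiased signal-detection observer
#'
#' Per-trial binary responses from an unbiased observer whose sensitivity at
#' the given contrast follows a Naka-Rushton contrast-response function
#' `d'(c) = dmax * c^n / (c^n + c50^n)`. Hits and false alarms follow the
#' equal-variance Gaussian model with criterion at the midpoint:
#' `H = pnorm(d'/2)`, `FA = pnorm(-d'/2)`.
#'
#' @param contrast Stimulus contrast, a proportion in `(0, 1]`.
#' @param psychometric List with elements `dmax`, `c50`, `n` (see
#'   [fit_naka_rushton()]).
#' @param n_trials Number of trials (half CW, half CCW signal classes).
#' @param seed Integer seed.
#' @return A tibble with columns `trial`, `contrast`, `signal` ("cw"/"ccw"),
#'   `response`, `correct`.
#' @export
simulate_observer <- function(contrast, psychometric, n_trials, seed) {
  if (contrast <= 0 || contrast > 1) stop_bad_arg("contrast must lie in (0, 1]")
  d <- naka_rushton(contrast, psychometric$dmax, psychometric$c50, psychometric$n)
  with_seed(seed, {
    signal <- rep(c("cw", "ccw"), length.out = n_trials)
    p_cw <- ifelse(signal == "cw", pnorm(d / 2), pnorm(-d / 2))
    resp <- ifelse(runif(n_trials) < p_cw, "cw", "ccw")
    tibble::tibble(
      trial = seq_len(n_trials), contrast = contrast, signal = signal,
      response = resp, correct = signal == resp
    )
  })
}

#' Simulate and preprocess a cohort of participants
#'
#' Runs the full generative pipeline for `n_participants` simulated
#' participants: per-participant IAF drawn around 10 Hz, a balanced blocked
#' schedule, session simulation, artifact interpolation, anti-aliased
#' downsampling to `target_fs`, and epoching. This is the standard input for
#' the group-level entrainment statistics.
#'
#' @param n_participants Number of simulated participants.
#' @param kappa Per-pulse reset strength shared by the cohort (0 = null
#'   cohort with no entrainment).
#' @param n_blocks,trials_per_block Design size (default 8 x 64 = 512 trials,
#'   128 per rhythmicity x stimulation cell).
#' @param montage Electrode layout (default the reduced 8-channel
#'   parieto-occipital montage for tractable simulation).
#' @param fs Native sampling rate in Hz (>= 1000).
#' @param target_fs Analysis sampling rate after downsampling (default 100).
#' @param seed Integer seed.
#' @param iaf_sd SD of the per-participant IAF draw around 10 Hz (clipped to
#'   `[7.5, 12.5]`; default 1).
#' @param ... Further arguments passed to [oscillator_model()].
#' @return A tibble with one row per participant: `participant`, `iaf`,
#'   `model` (list), `epochs` (list of [eeg_epochs()] at `target_fs`).
#' @export
simulate_cohort <- function(n_participants = 10, kappa = 0.8, n_blocks = 8,
                            trials_per_block = 64, montage = montage_1020(8),
                            fs = 1000, target_fs = 100, seed, iaf_sd = 1, ...) {
  seeds <- child_seeds(seed, 3 * n_participants)
  rows <- lapply(seq_len(n_participants), function(p) {
    s <- seeds[(p - 1) * 3 + 1:3]
    iaf <- with_seed(s[1], min(max(rnorm(1, 10, iaf_sd), 7.5), 12.5))
    model <- oscillator_model(iaf = iaf, kappa = kappa, ...)
    sched <- make_trial_schedule(n_blocks, trials_per_block, seed = s[2])
    raw <- simulate_session(model, sched, montage, fs = fs, seed = s[3])
    ep <- preprocess_session(raw, target_fs = target_fs)
    tibble::tibble(
      participant = p, iaf = iaf, model = list(model), epochs = list(ep)
    )
  })
  dplyr::bind_rows(rows)
}
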