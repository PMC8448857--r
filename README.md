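# entrainr

Simulation and analysis of concurrent TMS–EEG experiments that probe
**entrainment of intrinsic occipital alpha oscillations** by short rhythmic
pulse bursts.

Parieto-occipital alpha rhythms (7–13 Hz) shape cortical excitability and
visual performance. A four-pulse burst of 10 Hz TMS over right early visual
cortex is hypothesized to progressively align the phase of the intrinsic
alpha oscillator across trials — entrainment — which should show up in EEG
as elevated phase-locked activity during and for a few cycles after the
burst, relative to arrhythmic and sham control stimulation. `entrainr` is
for researchers who want to analyse such experiments, or to plan them by
simulation: it pairs the complete analysis chain with a controllable
synthetic EEG generator so that every stage is verifiable by parameter
recovery.

The two phase-locked signatures at the core of the package are

* **evoked oscillation amplitude** — the Morlet amplitude (square root of
  power) of the trial-averaged waveform, and
* **inter-trial phase coherence** — `ITPC = |Σᵢ exp(i θᵢ) / N|`, the modulus
  of the mean unit phasor of the single-trial phases θᵢ at a
  time–frequency point (0 = random phase, 1 = perfect alignment),

both computed from five-cycle complex Morlet wavelets, whose resolutions
follow the closed forms `FWHM_time = c·√(2 ln 2)/(π f)` (0.19 s at 10 Hz,
c = 5) and `FWHM_freq = 2·√(2 ln 2)·f/c` (4.71 Hz).

What's inside:

* **Synthetic generator** — phase-resetting alpha oscillators (per-pulse
  reset fraction κ ∈ [0, 1], optional phase-dependent efficacy), balanced
  blocked trial schedules, rhythmic / bimodally-jittered arrhythmic / sham
  four-pulse trains, 1/f noise, occipitally-weighted channel gains, spike
  artifacts, resting-state recordings, and a signal-detection observer.
* **Preprocessing** — pchip interpolation of pulse artifacts (−1 to +13 ms),
  zero-phase anti-aliased downsampling, epoching; applied identically to
  active and sham data.
* **Spectral measures** — wavelet transform, evoked amplitude, ITPC,
  pre-burst phase extraction, individual alpha frequency (IAF) from Welch's
  periodogram.
* **Statistics** — planned 100 ms window contrasts (W0–W6), topographic
  cluster-based permutation tests with sign-flipping nulls, six-bin
  pre-burst phase analysis with sinusoidal regression, repeated-measures
  ANOVA, IAF–ITPC correlations.
* **Psychophysics** — d′ and criterion with log-linear correction, and
  Naka–Rushton contrast-response fits `d′(c) = d′max·cⁿ/(cⁿ + c50ⁿ)` with
  contrast titration.

Results come back as tibbles; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

Simulate one participant with strong entrainment (κ = 0.8), preprocess, and
compare post-burst phase alignment between rhythmic and arrhythmic active
stimulation:

```r
library(entrainr)

model <- oscillator_model(iaf = 10.4, kappa = 0.8)
sched <- make_trial_schedule(n_blocks = 4, trials_per_block = 32, seed = 2)
raw   <- simulate_session(model, sched, montage_1020(8), fs = 1000, seed = 2)
ep    <- preprocess_session(raw)   # interpolate, 100 Hz, epoch [-300, 900)
ep
#> <eeg_epochs> 128 trials x 8 channels x 120 samples @ 100 Hz, t = [-300, 890] ms

bank <- wavelet_bank(freqs = 10)
w4_itpc <- function(e) {
  pc <- itpc(wavelet_transform(e, bank))
  sel <- pc$valid[1, ] & pc$times >= 405 & pc$times < 505   # W4 window
  mean(pc$data[match(c("O2", "PO4"), e$ch_names), 1, sel])
}
w4_itpc(epochs_subset(ep, ep$info$rhythmicity == "rhythmic" &
                          ep$info$stimulation == "active"))
#> [1] 0.9370
w4_itpc(epochs_subset(ep, ep$info$rhythmicity == "arrhythmic" &
                          ep$info$stimulation == "active"))
#> [1] 0.6066

estimate_iaf(simulate_rest(model, seed = 3))
#> [1] 10.5
```

In the first cycle after the last pulse (window W4, 405–505 ms), phases of
rhythmically stimulated trials are nearly aligned at 10 Hz over the
channels closest to the stimulated site (ITPC 0.94), while arrhythmic
stimulation — same pulse count, same first and last pulse times, jittered
middle pulses — leaves them far more dispersed (ITPC 0.61). The IAF
estimate recovers the generating oscillator frequency (10.4 Hz) to the
0.5 Hz resolution of the periodogram.

Group-level analyses take a simulated cohort: `simulate_cohort()` →
`window_metrics()` → `planned_contrasts()` (the per-window paired t-table),
`cluster_permutation()` for topographies, `phase_bin_cohort()` for the
pre-burst phase dependence, `correlate_iaf_itpc()` for trait correlations.
`run_pipeline(default_config(seed))` (or
`Rscript scripts/run_pipeline.R --seed 7 --out results/`) executes every
stage end to end and writes tidy CSV/JSON tables that are byte-identical
for identical (config, seed).

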