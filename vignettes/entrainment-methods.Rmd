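---
title: "Methods: simulating and measuring TMS-driven alpha entrainment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring TMS-driven alpha entrainment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrainr)
```

## The question the package addresses

Occipital alpha rhythms (roughly 7–13 Hz) wax, wane and drift in phase from
moment to moment. A short burst of rhythmic transcranial magnetic stimulation
(TMS) — four pulses 100 ms apart over right early visual cortex — is
hypothesized to *entrain* the intrinsic alpha oscillator: each pulse nudges
the ongoing phase toward a preferred value, so that across trials the phase
becomes progressively aligned during the burst and remains aligned for a few
cycles afterwards. Two EEG signatures quantify this: **evoked oscillation
amplitude** (the wavelet amplitude of the trial-averaged waveform, which only
phase-locked activity survives) and **inter-trial phase coherence** (ITPC,
the modulus of the mean unit phasor of single-trial phases).

Because no public recordings accompany this design, the package pairs the
full analysis chain with a synthetic generator whose entrainment strength is
controllable, so every stage can be verified by parameter recovery: a null
generator must produce null statistics, and a strongly entraining generator
must reproduce the expected window-by-window pattern.

## The generative model

Each trial simulates a single cortical alpha oscillator observed through a
noisy multi-channel montage:

* **Oscillator.** Phase advances at the participant's intrinsic alpha
  frequency (IAF, drawn once per participant around 10 Hz, SD 1 Hz, clipped
  to 7.5–12.5) plus a per-trial frequency perturbation (`freq_jitter`,
  default SD 0.5 Hz). The initial phase is uniform on the circle.
* **Phase resetting.** At each *active* pulse the phase jumps by
  `kappa * wrap(reset_phase - phase)`. `kappa = 0` leaves the oscillator
  untouched; `kappa = 1` is a hard reset. An optional modulation
  (`kappa_mod`) scales the effective `kappa` by
  `1 + kappa_mod * cos(phase_pre - reset_phase)`, making the reset more
  effective when the burst arrives at a congruent ongoing phase — the
  mechanism probed by the phase-bin analysis.
* **Background.** Independent per-channel `1/f` noise (spectral slope 1,
  RMS 10 µV) plus the 10 µV oscillation projected through a Gaussian gain
  map centred between O2 and PO4 (the scalp sites nearest the stimulated
  cortex). The gain map is a schematic distance falloff, not a conduction
  model.
* **Artifacts.** Active pulses add a seeded damped-oscillation spike
  (500 µV, 8 ms, within the 4–10 ms range typical of TMS spikes). Sham
  trials receive neither reset nor artifact and are otherwise statistically
  identical — a clean negative control with no auditory or somatosensory
  evoked response.

The per-trial frequency perturbation deserves emphasis. Without it, phase
advances deterministically, so the phase measured 200 ms before the burst
would *fix* the phase at every later time; trials sorted into a pre-burst
phase bin would be phase-aligned forever after, and within-bin ITPC would be
high whether or not any entrainment occurred. With a 0.5 Hz trial-to-trial
SD — an ordinary figure for moment-to-moment alpha variability — phases
decorrelate by roughly 1.9 rad over half a second unless a reset re-aligns
them, which is exactly the contrast the analysis must detect.

Why rhythmic and arrhythmic bursts separate: the first and last pulses are
identical in both conditions (105 and 405 ms after the pre-cue), while the
arrhythmic middle pulses are jittered by a bimodal ±30 ms (SD 10 ms) mixture.
At 10 Hz a ±30 ms shift is ±1.9 rad, so after an arrhythmic middle pulse the
across-trial phase distribution is split into two widely separated lobes; a
partial reset at the common final pulse shrinks deviations by `1 - kappa`
but cannot collapse the lobes, leaving arrhythmic ITPC low while rhythmic
trials — whose pulses arrive in step with the oscillator — converge.
Jittered trains are resampled jointly until all gaps are at least 20 ms,
which keeps the artifact-interpolation windows non-overlapping.

## Preprocessing

* **Artifact interpolation.** Samples from 1 ms before to 13 ms after each
  pulse (closed interval; 36 samples at 2500 Hz) are replaced by
  shape-preserving piecewise cubic Hermite (Fritsch–Carlson) interpolation
  anchored on 20 clean samples per side. Linear signals are restored to
  numerical precision, and samples outside the windows are returned
  bit-identical. The identical operation is applied to sham data at the
  virtual pulse times so the processing footprint cannot differ between
  conditions.
* **Downsampling.** A 4th-order Butterworth low-pass at 0.4 × the target
  rate, applied forward and backward (an effective 8th-order zero-phase
  response), precedes decimation to 100 Hz. Consequence: content above
  ~40 Hz is attenuated, so wavelet results near 50 Hz on 100 Hz data sit
  close to Nyquist and should be interpreted with care.
* **Epoching.** Half-open windows `[-300, 900)` ms around each pre-cue
  onset, 120 samples at 100 Hz, time re-referenced so the cue is t = 0. No
  re-referencing of channels is applied anywhere.

## Wavelet measures

Five-cycle complex Morlet wavelets are used throughout (frequencies 3–50 Hz
available; the alpha analyses read 10 Hz). With `c` cycles at frequency `f`
the Gaussian envelope SD is `c/(2*pi*f)`, giving closed-form resolutions

* temporal FWHM `c * sqrt(2 ln 2) / (pi * f)` — 0.19 s at 10 Hz,
* spectral FWHM `2 * sqrt(2 ln 2) * f / c` — 4.71 Hz at 10 Hz.

Numerical choices:

* **Normalization.** Kernels are scaled to unit gain at their centre
  frequency, so amplitudes read in microvolts; a unit 10 Hz cosine yields
  amplitude 1.0 at 10 Hz.
* **Zero-mean correction.** The truncated Gaussian-windowed carrier has a
  small nonzero sum; the mean is subtracted under the envelope so DC input
  produces exactly zero response in the epoch interior.
* **Edge handling.** No padding. A coefficient is flagged invalid when it
  lies within half the wavelet's FWHM duration (95 ms at 10 Hz) of an epoch
  edge, and flagged samples are excluded from every statistic. This margin
  treats the FWHM as the wavelet's effective duration; coefficients just
  inside the margin still lose a small tail of kernel mass (under 1% at the
  pre-burst phase time), which is visible only as a ~0.03 rad phase
  sensitivity to large DC offsets near the edge.
* **Phase convention.** The coefficient's angle equals the instantaneous
  phase of a cosine at the centre frequency. Pre-burst phase is read at
  10 Hz, 200 ms before the first pulse (t = −95 ms); times between samples
  are handled by linear interpolation of the bracketing unit phasors.

**Evoked vs ITPC.** Evoked amplitude transforms the trial-average waveform;
ITPC transforms each trial and takes `|mean(exp(i*theta))|` across trials.
ITPC is bounded in [0, 1], invariant to per-trial amplitude scaling, and its
small-sample null mean is `sqrt(pi)/(2*sqrt(N))` — the package's tests check
both properties against Monte-Carlo.

**IAF estimation.** Welch's periodogram (2 s Hann segments, 50% overlap,
0.5 Hz resolution) of a two-minute rest recording; the IAF is the argmax in
7–13 Hz, with a warning when the argmax is a band boundary rather than a
local peak.

## Statistics

* **Planned window contrasts.** Seven contiguous 100 ms windows W0–W6 span
  5–705 ms: before the burst (W0), between pulses (W1–W3) and the three
  cycles after the last pulse (W4–W6). Per participant, ITPC and evoked
  amplitude are averaged over O2/PO4 × 10 Hz × the valid samples of each
  window, and rhythmic vs arrhythmic active conditions are compared by
  paired t-tests, two-tailed (the conservative choice; the cluster tests
  below are one-tailed by design). The windows are planned a priori, so no
  correction is applied across them.
* **Cluster-based permutation tests.** For whole-scalp topographies,
  channel-wise paired t-values are thresholded at the cluster-forming level
  (0.05), suprathreshold channels are grouped into connected components
  under an adjacency graph (channels closer than 1.3 × the median
  nearest-neighbour distance on the schematic layout), clusters are scored
  by summed t, and the null distribution of the maximum cluster mass is
  built from 1000 random sign-flips of the participant difference maps —
  the exact scheme for a paired design. Cluster p-values are
  `(1 + #(null >= observed)) / (n_perm + 1)`, so they can never be zero.
  Calibration: across 500 simulated null cohorts (10 participants, 63
  channels) the family-wise false-positive rate is ~0.04 at a nominal 0.05.
* **Phase-bin analysis.** Trials of the rhythmic-active condition are
  sorted into six equal circular bins of their pre-burst phase (first bin
  starting at −π by default; the origin is a parameter). Within each bin,
  ITPC is computed per participant at 10 Hz for every sample of the
  post-divergence window. The window is `[205, 705]` ms with inclusive
  endpoints; on a cue-aligned 100 Hz grid these are the 50 samples
  210–700 ms. Per-participant bin means feed a one-way repeated-measures
  ANOVA (dof `(5, 5(n-1))` for six bins) and the six grand means are fitted
  with `y = a sin(f x pi/3 + phi) + c` by multi-start nonlinear least
  squares. A pooled variant (trials combined across participants before
  ITPC) is available behind a flag; it discards the repeated-measures
  structure and is reported without an ANOVA.
* **Sine-fit identifiability.** The fit is canonicalized (`a >= 0`,
  `phi` in `[0, 2pi)`) and the frequency is constrained to 0.25–3 cycles
  per six bins: left unbounded, the model has a degenerate direction
  (`a -> Inf`, `f -> 0` approximates any smooth trend) that can out-fit a
  genuine circular modulation. Six linear points cannot in general identify
  the circular frequency of a skewed profile, so tests of "one-cycle"
  structure additionally compare the first and second circular harmonics of
  the bin means. Flat inputs return an explicit `a = 0` solution.
* **IAF correlation.** Pearson correlations (two-tailed) of
  per-participant entrained ITPC (rhythmic-active mean over W2–W6 at 10 Hz)
  with IAF and with |IAF − 10 Hz|.

### Wavelet leakage and the W1 window

A consequence worth stating plainly: the two active conditions first diverge
at the second pulse (205 ms). A 10 Hz coefficient centred late in W1
(105–205 ms) draws roughly a quarter of its kernel mass from beyond 205 ms,
so some condition difference necessarily leaks backward into W1. At strong
reset strengths (`kappa` near 0.8) the post-divergence difference is so
large and so consistent across simulated participants that the leaked
fraction alone makes the W1 contrast significant. This is a property of
windowed wavelet analysis, not an implementation defect; with weak effects
(small `kappa`) the leaked difference disappears into between-participant
noise and W1 is quiet. W0 ends before any condition difference exists at
the pulse-train scale and stays null at every reset strength, and the
progressive-enhancement inequality (W2–W4 contrast exceeding W0–W1) holds
throughout.

## Psychophysics

The behavioral stage models an unbiased equal-variance signal-detection
observer: hit rate `pnorm(d'/2)`, false-alarm rate `pnorm(-d'/2)`, with
sensitivity following a Naka–Rushton contrast-response function
`d'(c) = dmax * c^n / (c^n + c50^n)`. From response tables, `d' = z(H) -
z(FA)` and criterion `c = -(z(H) + z(FA))/2`; when an observed rate is 0 or
1 the log-linear correction (0.5 added to each cell) keeps the quantiles
finite, and the correction can be forced on or off. Naka–Rushton curves are
fitted in log-contrast space — where the function is a logistic, much better
conditioned — with multi-start over the exponent, and the fitted curve can
be inverted to titrate the contrast for a target sensitivity (d' = 1.2 by
default). The definitional identity `d'(c50) = dmax/2` is exact in the fit.

## Reproducibility and problem sizes

Every stochastic function takes a seed, and a single master seed is fanned
out to stage-level child seeds by a fixed scheme (`child_seeds`), so a whole
pipeline run is a pure function of (config, seed); the demo pipeline writes
byte-identical tables when re-run. Simulated cohorts in the test suite use
a 1000 Hz native rate (artifact windows stay resolvable and decimation to
100 Hz remains integer), an 8-channel parieto-occipital montage, and 10
participants × 512 trials for the window-contrast checks; the phase-bin
checks use 4 participants with 96 rhythmic-active trials each (about 16
trials per bin — sparser designs leave near-empty bins and unstable
within-bin ITPC). The cluster-test calibration uses 500 null cohorts of 10
participants × 63 channels at 1000 permutations each.

## Known limitations

* One oscillator, one source: no volume-conduction head model, no multi-source
  mixing beyond the schematic gain map, no harmonics of the driven rhythm.
* Sham is signal-identical to no-stimulation; auditory or somatosensory
  responses to the sham clicks are not modelled.
* The spike artifact is a stylized damped oscillation; real TMS artifacts
  vary in shape, and recovery through interpolation is only as good as the
  clean-sample anchors.
* Passing tests on synthetic cohorts demonstrate that the pipeline measures
  what the generative model produces; they cannot certify behaviour on real
  recordings with eye movements, non-stationary noise, or electrode drift.
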