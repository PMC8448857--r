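test_that("wavelet geometry matches the closed forms and scales with f", {
  b <- wavelet_bank(freqs = c(5, 10, 20))
  expect_equal(b$fwhm_time, 5 * sqrt(2 * log(2)) / (pi * c(5, 10, 20)))
  expect_equal(b$fwhm_freq, 2 * sqrt(2 * log(2)) * c(5, 10, 20) / 5)
  # doubling f halves the temporal width and doubles the spectral width
  expect_equal(b$fwhm_time[2] / b$fwhm_time[3], 2)
  expect_equal(b$fwhm_freq[3] / b$fwhm_freq[2], 2)
  # measured on the sampled kernel, not just the formula
  m <- morlet_fwhm(10, 5, fs = 1000)
  expect_equal(unname(m["fwhm_time"]), 5 * sqrt(2 * log(2)) / (10 * pi),
               tolerance = 1e-3)
  expect_equal(unname(m["fwhm_freq"]), 2 * sqrt(2 * log(2)) * 2,
               tolerance = 1e-3)
  expect_equal(round(unname(m["fwhm_time"]), 2), 0.19)
  expect_equal(round(unname(m["fwhm_freq"]), 2), 4.71)
})

test_that("unit-gain normalization returns sinusoid amplitude in microvolts", {
  ep <- cosine_epochs(1, freq = 10, amp = 2, fs = 100, n_samp = 300)
  tf <- wavelet_transform(ep, wavelet_bank(freqs = 10))
  mid <- which(tf$valid[1, ])
  mid <- mid[mid > 50 & mid < 250]
  expect_equal(mean(Mod(tf$data[1, 1, 1, mid])), 2, tolerance = 0.01)
  # zero signal transforms to zero
  ep0 <- epochs_from_matrix(matrix(0, 1, 200), 1, fs = 100)
  tf0 <- wavelet_transform(ep0, wavelet_bank(freqs = c(5, 10)))
  expect_true(all(Mod(tf0$data) == 0))
  expect_error(
    wavelet_transform(ep, wavelet_bank(freqs = 60)),
    "Nyquist"
  )
})

test_that("ITPC reproduces the analytic phasor cases", {
  # identical trials: perfect phase alignment
  ep <- cosine_epochs(50, phase = 1.1)
  pc <- itpc(wavelet_transform(ep, wavelet_bank(freqs = 10)))
  mid <- which(pc$valid[1, ])
  expect_equal(max(abs(pc$data[1, 1, mid] - 1)), 0, tolerance = 1e-9)
  # antipodal pair cancels
  ep2 <- cosine_epochs(2, phase = c(0, pi))
  pc2 <- itpc(wavelet_transform(ep2, wavelet_bank(freqs = 10)))
  expect_lt(max(pc2$data[1, 1, mid]), 1e-6)
  # quadrature pair: |(1 + i)/2|
  ep3 <- cosine_epochs(2, phase = c(0, pi / 2))
  pc3 <- itpc(wavelet_transform(ep3, wavelet_bank(freqs = 10)))
  expect_equal(mean(pc3$data[1, 1, mid]), sqrt(2) / 2, tolerance = 1e-3)
  expect_error(itpc(wavelet_transform(cosine_epochs(1),
                                      wavelet_bank(freqs = 10))), "2")
})

test_that("ITPC is a pure phase statistic bounded in [0, 1]", {
  set.seed(91)
  ph <- runif(40, 0, 2 * pi)
  amp <- runif(40, 0.5, 3)
  pc1 <- itpc(wavelet_transform(cosine_epochs(40, phase = ph),
                                wavelet_bank(freqs = 10)))
  pc2 <- itpc(wavelet_transform(cosine_epochs(40, phase = ph, amp = amp),
                                wavelet_bank(freqs = 10)))
  expect_true(all(pc1$data >= 0 & pc1$data <= 1))
  mid <- which(pc1$valid[1, ])
  expect_equal(pc1$data[1, 1, mid], pc2$data[1, 1, mid], tolerance = 1e-6)
})

test_that("uniform random phases give the expected small-sample ITPC bias", {
  for (n in c(16, 64)) {
    set.seed(n)
    means <- replicate(60, {
      ph <- runif(n, 0, 2 * pi)
      Mod(mean(exp(1i * ph)))
    })
    expect_equal(mean(means), sqrt(pi) / (2 * sqrt(n)), tolerance = 0.1)
  }
})

test_that("evoked amplitude is the transform of the trial average", {
  # identical trials: averaging is the identity
  ep <- cosine_epochs(5, amp = 1.5, phase = 0.4)
  ev <- evoked_amplitude(ep, wavelet_bank(freqs = 10))
  tf1 <- wavelet_transform(cosine_epochs(1, amp = 1.5, phase = 0.4),
                           wavelet_bank(freqs = 10))
  mid <- which(ev$valid[1, ])
  expect_equal(ev$data[1, 1, mid], Mod(tf1$data[1, 1, 1, mid]),
               tolerance = 1e-9)
  # antiphase trials cancel
  ev2 <- evoked_amplitude(cosine_epochs(2, phase = c(0, pi)),
                          wavelet_bank(freqs = 10))
  expect_lt(max(ev2$data[1, 1, mid]), 1e-9)
  expect_error(
    evoked_amplitude(
      eeg_epochs(array(0, c(0, 1, 120)),
                 seq(-300, 890, 10), 100, "ch1"),
      wavelet_bank(freqs = 10)
    ),
    "trial"
  )
})

test_that("evoked amplitude never exceeds the mean single-trial amplitude", {
  set.seed(92)
  ph <- runif(30, 0, 2 * pi)
  ep <- cosine_epochs(30, phase = ph)
  bank <- wavelet_bank(freqs = c(8, 10, 12))
  ev <- evoked_amplitude(ep, bank)
  tf <- wavelet_transform(ep, bank)
  mean_st <- apply(Mod(tf$data), c(2, 3, 4), mean)
  expect_true(all(ev$data <= mean_st + 1e-9))
  # with uniform phases the evoked amplitude is far below the induced level
  mid <- which(ev$valid[2, ])
  expect_lt(mean(ev$data[1, 2, mid]), 0.4 * mean(mean_st[1, 2, mid]))
})

test_that("pre-TMS phase extraction matches the analytic cosine phase", {
  fs <- 100
  for (t0 in c(-0.040, 0.013)) {
    times <- seq(-300, 890, 1000 / fs)
    x <- cos(2 * pi * 10 * (times / 1000 - t0))
    ep <- epochs_from_matrix(matrix(x, 1), 1, fs)
    tf <- wavelet_transform(ep, wavelet_bank(freqs = 10))
    expected <- ((2 * pi * 10 * (-0.095 - t0) + pi) %% (2 * pi)) - pi
    expect_equal(pre_tms_phase(tf, channels = "ch1"), expected,
                 tolerance = 0.05)
  }
  # adding a DC offset leaves the phase unchanged (zero-mean wavelet);
  # exact in the interior, approximate near the epoch edge where the
  # truncated kernel loses its zero-sum property
  times <- seq(-300, 890, 1000 / fs)
  x <- cos(2 * pi * 10 * times / 1000)
  epdc <- epochs_from_matrix(matrix(x + 5, 1), 1, fs)
  ep <- epochs_from_matrix(matrix(x, 1), 1, fs)
  bank <- wavelet_bank(freqs = 10)
  expect_equal(
    pre_tms_phase(wavelet_transform(epdc, bank), t = 300, channels = "ch1"),
    pre_tms_phase(wavelet_transform(ep, bank), t = 300, channels = "ch1"),
    tolerance = 1e-6
  )
  expect_lt(
    abs(pre_tms_phase(wavelet_transform(epdc, bank), channels = "ch1") -
          pre_tms_phase(wavelet_transform(ep, bank), channels = "ch1")),
    0.05
  )
  # phase-offset symmetry: +theta and -theta offsets are mirror images
  # around the carrier phase a = 2*pi*f*t, i.e. ph(+theta) + ph(-theta) = 2a
  theta <- 0.9
  a <- 2 * pi * 10 * (-0.095)
  epp <- epochs_from_matrix(matrix(cos(2 * pi * 10 * times / 1000 + theta), 1), 1, fs)
  epm <- epochs_from_matrix(matrix(cos(2 * pi * 10 * times / 1000 - theta), 1), 1, fs)
  phsum <- pre_tms_phase(wavelet_transform(epp, bank), channels = "ch1") +
    pre_tms_phase(wavelet_transform(epm, bank), channels = "ch1")
  expect_lt(abs(((phsum - 2 * a + pi) %% (2 * pi)) - pi), 0.05)
  # an edge-flagged time is refused
  expect_error(
    pre_tms_phase(wavelet_transform(ep, bank), t = -280, channels = "ch1"),
    "edge"
  )
})

test_that("IAF estimation finds the dominant alpha peak", {
  fs <- 500
  t <- (0:(120 * fs - 1)) / fs
  set.seed(93)
  x <- sin(2 * pi * 10 * t) + rnorm(length(t), 0, sqrt(0.5) / sqrt(10))
  expect_equal(estimate_iaf(eeg_raw(matrix(x, 1), fs, "Oz")), 10,
               tolerance = 0.5)
  # out-of-band oscillation: boundary argmax with warning
  x20 <- sin(2 * pi * 20 * t)
  expect_warning(estimate_iaf(eeg_raw(matrix(x20, 1), fs, "Oz")), "boundary")
  expect_error(
    estimate_iaf(eeg_raw(matrix(x[1:fs], 1), fs, "Oz")),
    "10 s"
  )
})
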