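test_that("model parameters are validated", {
  expect_error(oscillator_model(iaf = 6), "7")
  expect_error(oscillator_model(kappa = 1.5), "kappa")
  expect_error(oscillator_model(artifact_duration = 12), "artifact_duration")
})

test_that("simulation is bit-identical for identical (model, schedule, seed)", {
  mod <- oscillator_model()
  sched <- flat_schedule(4)
  r1 <- simulate_session(mod, sched, montage_1020(8), fs = 1000, seed = 30)
  r2 <- simulate_session(mod, sched, montage_1020(8), fs = 1000, seed = 30)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_session(mod, sched, montage_1020(8), fs = 1000, seed = 31)
  expect_false(identical(r1$data, r3$data))
})

test_that("sham trials carry no pulse transient", {
  mod <- oscillator_model(alpha_amp = 5, noise_amp = 5, artifact_amp = 800)
  sched_a <- flat_schedule(6)
  sched_s <- dplyr::mutate(sched_a, stimulation = "sham")
  mont <- montage_1020(8)
  ra <- simulate_session(mod, sched_a, mont, fs = 1000, seed = 40)
  rs <- simulate_session(mod, sched_s, mont, fs = 1000, seed = 40)
  times <- ra$t0 + (seq_len(ncol(ra$data)) - 1) * 1000 / ra$fs
  for (k in seq_len(nrow(ra$events))) {
    win <- times >= ra$events$p1[k] - 1 & times <= ra$events$p1[k] + 13
    expect_gt(max(abs(ra$data[1, win])), 100) # artifact dominates
    expect_lt(max(abs(rs$data[1, win])), 100) # sham: oscillation + noise only
  }
  # sham pulse windows look like neighboring windows (same scale)
  near <- times >= 60 & times < 88
  sham_win <- times >= 104 & times <= 132
  expect_lt(max(abs(rs$data[1, sham_win])) / max(abs(rs$data[1, near])), 10)
})

test_that("t_span and fs preconditions are enforced", {
  mod <- oscillator_model()
  tr <- flat_schedule(1)
  expect_error(
    simulate_epoch(mod, tr, fs = 500, seed = 1),
    "1000"
  )
  expect_error(
    simulate_epoch(mod, tr, t_span = c(-100, 900), seed = 1),
    "t_span"
  )
})

test_that("without resets the post-burst phase stays circularly uniform", {
  mod <- oscillator_model(kappa = 0, alpha_amp = 10, noise_amp = 5)
  sched <- flat_schedule(200)
  raw <- simulate_session(mod, sched, montage_1020(8), fs = 1000, seed = 50)
  ep <- preprocess_session(raw)
  tf <- wavelet_transform(ep, wavelet_bank(freqs = 10))
  ti <- which.min(abs(tf$times - 450)) # inside W4
  ph <- Arg(tf$data[, match("O2", ep$ch_names), 1, ti])
  expect_gt(rayleigh_p(ph), 0.01)
})

test_that("full reset drives post-burst ITPC above 0.9", {
  ep <- shared_entrained_epochs()
  tf <- wavelet_transform(ep, wavelet_bank(freqs = 10))
  pc <- itpc(tf)
  tsel <- pc$times >= 405 & pc$times < 505
  ci <- match(c("O2", "PO4"), ep$ch_names)
  expect_gt(mean(pc$data[ci, 1, tsel]), 0.9)
})

test_that("post-burst ITPC is non-decreasing in the reset strength", {
  kappas <- c(0, 0.25, 0.5, 0.75, 1)
  sched <- flat_schedule(100)
  mont <- montage_1020(8)
  vals <- vapply(seq_along(kappas), function(i) {
    mod <- oscillator_model(kappa = kappas[i], alpha_amp = 10, noise_amp = 5)
    raw <- simulate_session(mod, sched, mont, fs = 1000, seed = 60)
    ep <- preprocess_session(raw)
    pc <- itpc(wavelet_transform(ep, wavelet_bank(freqs = 10)))
    tsel <- pc$times >= 405 & pc$times < 505
    mean(pc$data[match(c("O2", "PO4"), ep$ch_names), 1, tsel])
  }, 0.0)
  expect_true(all(diff(vals) > -0.02)) # non-decreasing within MC error
  expect_gt(vals[5], vals[1] + 0.5)
})

test_that("resting-state simulation recovers the model IAF", {
  r1 <- simulate_rest(oscillator_model(iaf = 10), seed = 70)
  expect_equal(estimate_iaf(r1), 10, tolerance = 0.051)
  r2 <- simulate_rest(oscillator_model(iaf = 11.5), seed = 71)
  expect_equal(estimate_iaf(r2), 11.5, tolerance = 0.051)
  # different seeds: different samples, same spectral peak
  r3 <- simulate_rest(oscillator_model(iaf = 11.5), seed = 72)
  expect_false(identical(r2$data, r3$data))
  expect_equal(estimate_iaf(r2), estimate_iaf(r3))
  # noiseless: periodogram peak exactly at the iaf bin
  r4 <- simulate_rest(oscillator_model(iaf = 10.5, noise_amp = 0), seed = 73)
  expect_equal(estimate_iaf(r4), 10.5)
  expect_error(simulate_rest(oscillator_model(), duration = 5, seed = 1), "10")
})

test_that("simulated observer matches closed-form signal detection rates", {
  psy <- list(dmax = 2.4, c50 = 0.16, n = 2)
  # at c50 the generating sensitivity is dmax/2
  obs <- simulate_observer(0.16, psy, n_trials = 10000, seed = 80)
  cnt <- sdt_counts(obs)
  d <- dprime_criterion(cnt$hits, cnt$misses, cnt$fas, cnt$crs)
  expect_equal(d$dprime, 1.2, tolerance = 0.05)
  expect_lt(abs(d$criterion), 0.05)
  # a zero-sensitivity observer performs at chance
  obs0 <- simulate_observer(1e-6, psy, n_trials = 10000, seed = 81)
  expect_equal(mean(obs0$correct), 0.5, tolerance = 0.02)
  expect_error(simulate_observer(0, psy, 10, seed = 1), "contrast")
})
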