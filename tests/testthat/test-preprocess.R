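make_raw <- function(x, fs, t0 = 0) {
  eeg_raw(matrix(x, 1), fs, "ch1", t0 = t0)
}

test_that("interpolation with no pulses returns the input bit-identically", {
  set.seed(1)
  raw <- make_raw(rnorm(1000), fs = 2500)
  out <- interpolate_artifacts(raw, numeric(0))
  expect_identical(out$data, raw$data)
})

test_that("interpolation replaces exactly the [-1, +13] ms window", {
  fs <- 2500
  set.seed(2)
  raw <- make_raw(rnorm(2000), fs = fs, t0 = -300)
  out <- interpolate_artifacts(raw, 105)
  changed <- which(out$data[1, ] != raw$data[1, ])
  times <- -300 + (seq_len(2000) - 1) * 1000 / fs
  # closed window 104.0 .. 118.0 ms at 0.4 ms spacing: 36 samples
  expect_equal(length(changed), 36)
  expect_equal(range(times[changed]), c(104, 118))
  untouched <- setdiff(seq_len(2000), changed)
  expect_identical(out$data[1, untouched], raw$data[1, untouched])
})

test_that("monotone cubic interpolation restores linear signals exactly", {
  fs <- 2500
  times <- -300 + (seq_len(2000) - 1) * 1000 / fs
  ramp <- 0.5 * times + 3
  spiked <- ramp
  spiked[times >= 104 & times <= 118] <- 500 # injected artifact
  out <- interpolate_artifacts(make_raw(spiked, fs, t0 = -300), 105)
  expect_lt(max(abs(out$data[1, ] - ramp)), 1e-9)
})

test_that("interpolation windows beyond the recording raise an error", {
  raw <- make_raw(rnorm(100), fs = 2500, t0 = 0)
  expect_error(interpolate_artifacts(raw, 2), "beyond")
})

test_that("sham and active trials get identical processing footprints", {
  fs <- 1000
  set.seed(3)
  base <- rnorm(3000)
  active <- base
  active[1400:1410] <- active[1400:1410] + 300
  t_virtual <- 1400 # same virtual pulse time for both
  out_a <- interpolate_artifacts(make_raw(active, fs), t_virtual)
  out_s <- interpolate_artifacts(make_raw(base, fs), t_virtual)
  changed_a <- which(out_a$data[1, ] != active)
  changed_s <- which(out_s$data[1, ] != base)
  expect_identical(changed_a, changed_s)
})

test_that("downsampling preserves alpha-band content and rejects aliases", {
  fs <- 2500
  t <- (0:(fs * 2 - 1)) / fs
  x10 <- sin(2 * pi * 10 * t)
  out <- downsample(make_raw(x10, fs), 100)
  expect_equal(out$fs, 100)
  mid <- 50:150 # away from filter edge transients
  ref <- sin(2 * pi * 10 * (mid - 1) / 100)
  expect_lt(max(abs(out$data[1, mid] - ref)), 0.01)
  x60 <- sin(2 * pi * 60 * t)
  out60 <- downsample(make_raw(x60, fs), 100)
  rms_in <- sqrt(mean(x60^2))
  rms_out <- sqrt(mean(out60$data[1, mid]^2))
  expect_lt(rms_out / rms_in, 0.05)
  expect_error(downsample(make_raw(x10, fs), 400), "divide")
})

test_that("epoching uses the half-open window with t = 0 at the cue", {
  fs <- 100
  raw <- make_raw(seq_len(500), fs) # sample k has value k, time (k-1)*10 ms
  ep <- epoch(raw, cue_onsets = 1000, window = c(-300, 900))
  expect_equal(dim(ep$data), c(1, 1, 120))
  expect_equal(ep$times[31], 0) # sample index 30 on a zero-based axis
  expect_equal(ep$data[1, 1, 31], 101) # value at t = 1000 ms
  ep2 <- epoch(raw, cue_onsets = c(1000, 2000))
  expect_equal(dim(ep2$data)[1], 2)
  expect_equal(ep2$times, ep$times)
  expect_warning(
    ep3 <- epoch(raw, cue_onsets = c(100, 1000)),
    "skipped"
  )
  expect_equal(dim(ep3$data)[1], 1)
})

test_that("interpolate-then-downsample matches the analysis-rate result", {
  # on artifact-free signals the order of the two stages is immaterial
  fs <- 1000
  t <- (0:2999) / fs
  x <- 7 * sin(2 * pi * 10 * t) + 2 * sin(2 * pi * 4 * t)
  r1 <- downsample(interpolate_artifacts(make_raw(x, fs), 1500), 100)
  r2 <- downsample(make_raw(x, fs), 100)
  mid <- 30:270
  # interpolation error on a smooth 7 uV oscillation stays under ~1.5%
  expect_lt(max(abs(r1$data[1, mid] - r2$data[1, mid])), 0.1)
})
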