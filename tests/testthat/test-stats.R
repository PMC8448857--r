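test_that("planned window contrasts behave like a paired t-test", {
  a <- c(0.5, 0.6, 0.7, 0.55, 0.65)
  # identical inputs: t = 0, p = 1
  r0 <- window_contrast(a, a, window = "W2")
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # constant shift: equals the one-sample t of the shift
  delta <- 0.07
  set.seed(21)
  b <- a + rnorm(5, 0, 0.02)
  r1 <- window_contrast(b + delta, b)
  d <- rep(delta, 5)
  expect_equal(r1$t, mean(b + delta - b) / (sd(b + delta - b) / sqrt(5)))
  # matches t.test on noisy data
  set.seed(22)
  x <- rnorm(8)
  y <- rnorm(8)
  tt <- t.test(x, y, paired = TRUE)
  r2 <- window_contrast(x, y)
  expect_equal(r2$t, unname(tt$statistic))
  expect_equal(r2$p, tt$p.value)
  expect_error(window_contrast(1:2, 2:3), "3")
})

test_that("identical topographies produce no suprathreshold clusters", {
  mont <- montage_1020(63)
  adj <- channel_adjacency(mont)
  set.seed(31)
  a <- matrix(rnorm(10 * 63), 10, 63, dimnames = list(NULL, mont$channel))
  ct <- cluster_permutation(a, a, adj, n_perm = 100, seed = 1)
  expect_equal(nrow(ct$clusters), 0)
})

test_that("cluster p-values live in [1/(nperm+1), 1] and are seeded", {
  mont <- montage_1020(63)
  adj <- channel_adjacency(mont)
  set.seed(32)
  a <- matrix(rnorm(10 * 63), 10, 63, dimnames = list(NULL, mont$channel))
  b <- matrix(rnorm(10 * 63), 10, 63, dimnames = list(NULL, mont$channel))
  ct1 <- cluster_permutation(a, b, adj, n_perm = 200, seed = 5)
  ct2 <- cluster_permutation(a, b, adj, n_perm = 200, seed = 5)
  expect_identical(ct1$clusters, ct2$clusters)
  if (nrow(ct1$clusters) > 0) {
    expect_true(all(ct1$clusters$p >= 1 / 201 & ct1$clusters$p <= 1))
  }
  # clusters are connected under the adjacency graph
  for (chs in ct1$clusters$channels) {
    idx <- match(chs, mont$channel)
    if (length(idx) > 1) {
      sub <- adj[idx, idx, drop = FALSE]
      reach <- (diag(length(idx)) + sub) %*%
        (diag(length(idx)) + sub) %*% (diag(length(idx)) + sub)
      for (k in 2:length(idx)) {
        reach <- reach %*% (diag(length(idx)) + sub)
      }
      expect_true(all(reach > 0))
    }
  }
})

test_that("a strong planted occipital effect is detected and covered", {
  mont <- montage_1020(63)
  adj <- channel_adjacency(mont)
  patch <- c("O1", "Oz", "O2")
  hits <- vapply(1:30, function(i) {
    s <- child_seeds(4000 + i, 3)
    set.seed(s[1])
    a <- matrix(rnorm(630), 10, 63, dimnames = list(NULL, mont$channel))
    set.seed(s[2])
    b <- matrix(rnorm(630), 10, 63, dimnames = list(NULL, mont$channel))
    a[, patch] <- a[, patch] + 2 # 2 SD participant-consistent effect
    ct <- cluster_permutation(a, b, adj, n_perm = 500, seed = s[3])
    sig <- unique(unlist(ct$clusters$channels[ct$clusters$significant]))
    all(patch %in% sig)
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("permutation p-values are super-uniform under the null", {
  # sign-symmetric null: p-value of the largest cluster should not be
  # anti-conservative (empirical CDF below the diagonal within MC error)
  mont <- montage_1020(8)
  adj <- channel_adjacency(mont)
  ps <- vapply(1:120, function(i) {
    s <- child_seeds(6000 + i, 2)
    set.seed(s[1])
    d <- matrix(rnorm(10 * 8), 10, 8, dimnames = list(NULL, mont$channel))
    ct <- cluster_permutation(d, 0 * d, adj, n_perm = 300, seed = s[2])
    if (nrow(ct$clusters) == 0) 1 else min(ct$clusters$p)
  }, 0.0)
  for (q in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= q), q + 2.5 * sqrt(q * (1 - q) / 120))
  }
})

test_that("sine regression recovers noiseless parameters exactly", {
  x <- 1:6
  y <- 0.05 * sin(x * pi / 3 + pi / 4) + 0.4
  f <- sine_regression(y)
  expect_equal(f$a, 0.05, tolerance = 1e-6)
  expect_equal(f$f, 1, tolerance = 1e-6)
  expect_equal(f$phi, pi / 4, tolerance = 1e-6)
  expect_equal(f$c, 0.4, tolerance = 1e-6)
  expect_lt(f$sse, 1e-12)
  # the canonical unit case
  f2 <- sine_regression(sin(x * pi / 3))
  expect_equal(f2$a, 1, tolerance = 1e-6)
  expect_equal(f2$f, 1, tolerance = 1e-6)
  expect_lt(min(f2$phi, 2 * pi - f2$phi), 1e-5) # phi = 0 on the circle
  expect_equal(f2$c, 0, tolerance = 1e-6)
  # flat input
  f3 <- sine_regression(rep(0.3, 6))
  expect_true(f3$flat)
  expect_equal(f3$a, 0)
  expect_equal(f3$c, 0.3)
})

test_that("sine-fit canonicalization is deterministic and SSE-invariant", {
  set.seed(41)
  x <- 1:6
  for (rep in 1:20) {
    a <- runif(1, -0.2, 0.2)
    f0 <- sample(c(0.5, 1, 2), 1)
    phi <- runif(1, -2 * pi, 2 * pi)
    c0 <- runif(1, 0, 1)
    y <- a * sin(f0 * x * pi / 3 + phi) + c0
    fit <- sine_regression(y)
    expect_gte(fit$a, 0)
    expect_gte(fit$f, 0)
    expect_true(fit$phi >= 0 && fit$phi < 2 * pi)
    # canonical parameters reproduce the curve
    expect_equal(fit$fitted, y, tolerance = 1e-5)
    expect_lt(fit$sse, 1e-8)
  }
})

test_that("repeated-measures ANOVA has the right dof and power behavior", {
  # flat table: F ~ 0, p ~ 1
  m <- matrix(rep(c(0.2, 0.4, 0.3, 0.5), 6), 4, 6)
  r <- rm_anova_bins(m)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  # 6 bins x 10 participants: dof (5, 45)
  set.seed(51)
  m2 <- matrix(rnorm(60), 10, 6)
  r2 <- rm_anova_bins(m2)
  expect_equal(r2$df1, 5)
  expect_equal(r2$df2, 45)
  # agrees with aov's within-subject stratum
  long <- data.frame(
    value = as.vector(m2),
    participant = factor(rep(1:10, 6)),
    bin = factor(rep(1:6, each = 10))
  )
  av <- summary(stats::aov(value ~ bin + Error(participant / bin), long))
  ftab <- av[["Error: participant:bin"]][[1]]
  expect_equal(r2$F, ftab["bin", "F value"], tolerance = 1e-8)
  expect_equal(r2$p, ftab["bin", "Pr(>F)"], tolerance = 1e-8)
  # a planted 1-SD sinusoidal bin effect is detected almost always
  det <- vapply(1:40, function(i) {
    set.seed(600 + i)
    base <- matrix(rnorm(60), 10, 6)
    eff <- matrix(rep(sin((1:6) * pi / 3), each = 10), 10, 6)
    rm_anova_bins(base + eff)$p < 0.01
  }, TRUE)
  expect_gte(mean(det), 0.9)
  expect_error(rm_anova_bins(matrix(c(NA, rnorm(11)), 2, 6)), "complete")
})

test_that("IAF correlation matches cor.test and controls its null", {
  # noiseless linear relation: r = 1
  d <- tibble::tibble(iaf = c(8, 9, 10, 11, 12), itpc = c(1, 2, 3, 4, 5) / 10)
  r <- correlate_iaf_itpc(d)
  expect_equal(r$r[r$predictor == "iaf"], 1)
  # null calibration at n = 10: |r| below the critical value ~95% of the time
  set.seed(61)
  rs <- replicate(1000, cor(rnorm(10), rnorm(10)))
  expect_equal(mean(abs(rs) < 0.632), 0.95, tolerance = 0.02)
  expect_error(
    correlate_iaf_itpc(tibble::tibble(iaf = c(10, 10, 10), itpc = 1:3 / 10)),
    "variance"
  )
  expect_error(correlate_iaf_itpc(d[1:2, ]), "3")
})

test_that("analysis windows are contiguous 100 ms partitions", {
  w <- analysis_windows()
  expect_equal(nrow(w), 7)
  expect_true(all(w$end - w$start == 100))
  expect_equal(w$start[-1], w$end[-7])
  expect_equal(w$start[1], 5)
  expect_equal(w$end[7], 705)
})
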