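#' Planned analysis time windows
#'
#' Seven contiguous 100 ms windows spanning the cycle before the first pulse
#' (W0), the three inter-pulse cycles (W1-W3) and the first three cycles
#' after the last pulse (W4-W6). Bounds are half-open `[start, end)` ms
#' relative to pre-cue onset.
#'
#' @return A tibble with columns `window`, `start`, `end`.
#' @export
analysis_windows <- function() {
  tibble::tibble(
    window = paste0("W", 0:6),
    start = seq(5, 605, by = 100),
    end = seq(105, 705, by = 100)
  )
}

#' Paired contrast of a per-participant metric
#'
#' Paired two-tailed t-test across participants between two conditions of the
#' same metric (e.g. ITPC averaged over O2/PO4 at 10 Hz within one time
#' window, rhythmic vs. arrhythmic). The seven planned windows are specified
#' a priori, so no multiple-comparison correction is applied across them.
#'
#' @param metric_a,metric_b Numeric vectors, one value per participant, in
#'   the same participant order.
#' @param window Optional window label carried into the output.
#' @return A one-row tibble: `window`, `n`, `mean_diff`, `t`, `df`, `p`.
#' @export
window_contrast <- function(metric_a, metric_b, window = NA_character_) {
  stopifnot(length(metric_a) == length(metric_b))
  n <- length(metric_a)
  if (n < 3) stop_bad_arg("window_contrast needs at least 3 participants")
  d <- metric_a - metric_b
  sdd <- sd(d)
  m <- mean(d)
  if (sdd == 0) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
  } else {
    t_stat <- m / (sdd / sqrt(n))
  }
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  tibble::tibble(window = window, n = n, mean_diff = m, t = t_stat,
                 df = n - 1, p = p)
}

#' Per-participant window metrics of phase-locked activity
#'
#' For each participant and each rhythmicity x stimulation cell, computes the
#' two phase-locked signatures at a target frequency - ITPC and evoked
#' oscillation amplitude - averaged over the channels of interest and over
#' the valid samples of each planned time window.
#'
#' @param cohort Tibble from [simulate_cohort()] (columns `participant`,
#'   `epochs`), or any tibble shaped that way.
#' @param f Target frequency in Hz (default 10).
#' @param channels Channels of interest (default `c("O2", "PO4")`; channels
#'   absent from the montage are dropped, falling back to all).
#' @param windows Window table from [analysis_windows()].
#' @return A tibble: `participant`, `rhythmicity`, `stimulation`, `window`,
#'   `itpc`, `evoked`.
#' @export
window_metrics <- function(cohort, f = 10, channels = c("O2", "PO4"),
                           windows = analysis_windows()) {
  bank <- wavelet_bank(freqs = f)
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    ep <- cohort$epochs[[i]]
    chans <- intersect(channels, ep$ch_names)
    if (length(chans) == 0) chans <- ep$ch_names
    ci <- match(chans, ep$ch_names)
    cells <- dplyr::distinct(ep$info[, c("rhythmicity", "stimulation")])
    purrr::map_dfr(seq_len(nrow(cells)), function(j) {
      sel <- ep$info$rhythmicity == cells$rhythmicity[j] &
        ep$info$stimulation == cells$stimulation[j]
      sub <- epochs_subset(ep, sel)
      tf <- wavelet_transform(sub, bank)
      pc <- itpc(tf)
      ev <- evoked_amplitude(sub, bank)
      itpc_t <- colMeans(matrix(pc$data[ci, 1, ], nrow = length(ci)))
      ev_t <- colMeans(matrix(ev$data[ci, 1, ], nrow = length(ci)))
      ok <- pc$valid[1, ]
      purrr::map_dfr(seq_len(nrow(windows)), function(w) {
        tsel <- ok & pc$times >= windows$start[w] & pc$times < windows$end[w]
        tibble::tibble(
          participant = cohort$participant[i],
          rhythmicity = cells$rhythmicity[j],
          stimulation = cells$stimulation[j],
          window = windows$window[w],
          itpc = mean(itpc_t[tsel]),
          evoked = mean(ev_t[tsel])
        )
      })
    })
  })
}

#' Planned window contrasts between rhythmic and arrhythmic stimulation
#'
#' The Table-1-shaped analysis: for each planned window and each phase-locked
#' signature, a paired two-tailed t-test of rhythmic vs. arrhythmic
#' conditions across participants (active stimulation by default).
#'
#' @param metrics Output of [window_metrics()].
#' @param stimulation Which stimulation type to contrast (default "active").
#' @return A tibble: `measure`, `window`, `n`, `mean_diff`, `t`, `df`, `p`.
#' @export
planned_contrasts <- function(metrics, stimulation = "active") {
  m <- metrics[metrics$stimulation == stimulation, ]
  purrr::map_dfr(c("itpc", "evoked"), function(v) {
    wide <- tidyr::pivot_wider(
      m[, c("participant", "rhythmicity", "window", v)],
      names_from = "rhythmicity", values_from = dplyr::all_of(v)
    )
    purrr::map_dfr(unique(wide$window), function(w) {
      ww <- wide[wide$window == w, ]
      dplyr::mutate(
        window_contrast(ww$rhythmic, ww$arrhythmic, window = w),
        measure = v, .before = 1
      )
    })
  })
}

# connected components among `sel` channels; returns max cluster mass and the
# member sets. adj_list is a list of integer neighbour vectors.
cluster_masses <- function(tvals, sel, adj_list) {
  if (length(sel) == 0) {
    return(list(mass = numeric(0), members = list()))
  }
  insel <- logical(length(tvals))
  insel[sel] <- TRUE
  seen <- logical(length(tvals))
  mass <- numeric(0)
  members <- list()
  for (s in sel) {
    if (seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      comp <- c(comp, v)
      nb <- adj_list[[v]]
      nb <- nb[insel[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    mass <- c(mass, sum(tvals[comp]))
    members <- c(members, list(comp))
  }
  list(mass = mass, members = members)
}

#' Topographic cluster-based permutation test
#'
#' Multiple-comparison-corrected paired comparison of two channel
#' topographies across participants. Channel-wise paired t-values are
#' thresholded at `cluster_alpha`; suprathreshold channels are grouped into
#' connected clusters under the adjacency graph and scored by their summed
#' t-value (cluster mass). The null distribution of the maximum cluster mass
#' is built by randomly sign-flipping each participant's difference map
#' `n_perm` times (the exact scheme for a paired design); cluster p-values
#' are `(1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param topo_a,topo_b Participants x channels matrices with identical
#'   column order; column names must match the adjacency dimnames if both are
#'   named.
#' @param adjacency Symmetric logical adjacency matrix (see
#'   [channel_adjacency()]).
#' @param n_perm Number of sign-flip permutations (default 1000).
#' @param tail `"one"` (a > b, positive clusters only; the default, as used
#'   for directional entrainment predictions) or `"two"`.
#' @param alpha Significance level for cluster p-values (default 0.05).
#' @param cluster_alpha Channel-wise threshold level (default 0.05).
#' @param seed Integer seed for the permutations.
#' @return An object of class `cluster_test`; its `clusters` element is a
#'   tibble with `cluster`, `channels` (list), `n_channels`, `mass`, `p`,
#'   `significant`.
#' @export
cluster_permutation <- function(topo_a, topo_b, adjacency, n_perm = 1000,
                                tail = c("one", "two"), alpha = 0.05,
                                cluster_alpha = 0.05, seed) {
  tail <- match.arg(tail)
  stopifnot(all(dim(topo_a) == dim(topo_b)))
  if (!is.null(colnames(topo_a)) && !is.null(colnames(adjacency))) {
    stopifnot(identical(colnames(topo_a), colnames(adjacency)))
  }
  n <- nrow(topo_a)
  nch <- ncol(topo_a)
  ch_names <- colnames(topo_a) %||% colnames(adjacency) %||% paste0("ch", 1:nch)
  adj_list <- lapply(seq_len(nch), function(i) which(adjacency[i, ]))
  d <- topo_a - topo_b
  ss <- colSums(d^2)
  t_of <- function(S) {
    m <- (S %*% d) / n
    v <- (rep(1, nrow(S)) %o% ss - n * m^2) / (n - 1)
    v[v < .Machine$double.eps] <- .Machine$double.eps
    m / sqrt(v / n)
  }
  t_obs <- drop(t_of(matrix(1, 1, n)))
  thresh <- if (tail == "one") {
    qt(1 - cluster_alpha, n - 1)
  } else {
    qt(1 - cluster_alpha / 2, n - 1)
  }
  find_clusters <- function(tv) {
    pos <- cluster_masses(tv, which(tv > thresh), adj_list)
    if (tail == "one") return(pos)
    neg <- cluster_masses(tv, which(tv < -thresh), adj_list)
    list(mass = c(pos$mass, neg$mass), members = c(pos$members, neg$members))
  }
  score <- function(mass) if (tail == "one") mass else abs(mass)
  obs <- find_clusters(t_obs)
  null_max <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    Tn <- t_of(S)
    vapply(seq_len(n_perm), function(i) {
      cl <- find_clusters(Tn[i, ])
      if (length(cl$mass) == 0) 0 else max(score(cl$mass))
    }, 0.0)
  })
  p <- vapply(obs$mass, function(m) {
    (1 + sum(null_max >= score(m))) / (n_perm + 1)
  }, 0.0)
  ord <- order(score(obs$mass), decreasing = TRUE)
  p_ord <- p[ord]
  clusters <- tibble::tibble(
    cluster = seq_along(ord),
    channels = lapply(obs$members[ord], function(i) ch_names[i]),
    n_channels = vapply(obs$members[ord], length, 0L),
    mass = obs$mass[ord],
    p = p_ord,
    significant = p_ord <= alpha
  )
  structure(
    list(clusters = clusters, t_obs = setNames(t_obs, ch_names),
         threshold = thresh, tail = tail, n_perm = n_perm, alpha = alpha,
         cluster_alpha = cluster_alpha, null_max = null_max),
    class = "cluster_test"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf(
    "<cluster_test> %s-tailed, %d permutations, threshold |t| > %.3f\n",
    x$tail, x$n_perm, x$threshold
  ))
  print(x$clusters)
  invisible(x)
}

#' Bin trials by pre-TMS phase and compute within-bin ITPC
#'
#' Trials are assigned to `n_bins` equal-width circular phase bins (first bin
#' starting at `origin`) according to their pre-pulse alpha phase. ITPC is
#' then computed within each bin at the target frequency, per time sample
#' across the analysis window, averaged over the channels of interest. The
#' window endpoints are inclusive for this analysis: `[205, 705]` ms sampled
#' at 100 Hz yields 51 time points.
#'
#' @param trial_tf Complex [tf_map()] of the trials (typically
#'   rhythmic-active only).
#' @param phases Per-trial pre-TMS phases in radians (see
#'   [pre_tms_phase()]); length must equal the number of trials.
#' @param window Analysis window in ms, endpoints inclusive (default
#'   `c(205, 705)`).
#' @param f Target frequency in Hz (default 10).
#' @param n_bins Number of phase bins (default 6).
#' @param origin Lower edge of the first bin in radians (default `-pi`).
#' @param channels Channels of interest (default `c("O2", "PO4")`).
#' @param min_trials Bins with fewer trials are flagged missing (default 2).
#' @return A tibble: `bin`, `time`, `n_trials`, `itpc` (NA for flagged
#'   bins).
#' @export
phase_bin_itpc <- function(trial_tf, phases, window = c(205, 705), f = 10,
                           n_bins = 6, origin = -pi,
                           channels = c("O2", "PO4"), min_trials = 2) {
  stopifnot(length(phases) == dim(trial_tf$data)[1])
  fi <- which.min(abs(trial_tf$freqs - f))
  tsel <- which(trial_tf$times >= window[1] - 1e-9 &
                  trial_tf$times <= window[2] + 1e-9 & trial_tf$valid[fi, ])
  chans <- intersect(channels, trial_tf$ch_names)
  if (length(chans) == 0) chans <- trial_tf$ch_names
  ci <- match(chans, trial_tf$ch_names)
  u <- (phases - origin) %% (2 * pi)
  bin <- pmin(floor(u / (2 * pi / n_bins)) + 1, n_bins)
  coefs <- trial_tf$data[, ci, fi, tsel, drop = FALSE]
  phasor <- coefs / Mod(coefs)
  phasor[!is.finite(phasor)] <- 0i
  purrr::map_dfr(seq_len(n_bins), function(b) {
    idx <- which(bin == b)
    if (length(idx) < min_trials) {
      return(tibble::tibble(
        bin = b, time = trial_tf$times[tsel], n_trials = length(idx),
        itpc = NA_real_
      ))
    }
    # ITPC per channel then averaged over channels, per time sample
    pc <- apply(Mod(apply(phasor[idx, , 1, , drop = FALSE], c(2, 4), mean)), 2, mean)
    tibble::tibble(
      bin = b, time = trial_tf$times[tsel], n_trials = length(idx), itpc = pc
    )
  })
}

#' Sinusoidal regression over phase bins
#'
#' Fits `y = a * sin(f * x * pi / 3 + phi) + c` to the bin means (x = bin
#' number 1..6) by nonlinear least squares with multi-start over
#' `phi in {0, pi/2, pi, 3*pi/2}` and `f in {0.5, 1, 2}`. The solution is
#' canonicalized so that `a >= 0`, `f >= 0` and `phi in [0, 2*pi)`. The
#' frequency is constrained to `[0.25, 3]` cycles per six bins: unbounded, the
#' model has a degenerate direction (`a -> Inf`, `f -> 0` approximates any
#' smooth trend) that can out-fit the genuine circular modulation. A
#' recovered frequency near 1 means ITPC varies over the bins with one full
#' cycle per circle of pre-TMS phase. Degenerate (flat) inputs return an
#' `a = 0` solution with the `flat` flag set.
#'
#' @param bin_means Numeric vector of bin means (length 6 in the standard
#'   analysis).
#' @param a_tol Amplitudes below this are treated as flat (default 1e-8).
#' @return An object of class `sine_fit`: fields `a`, `f`, `phi`, `c`,
#'   `sse`, `r2`, `flat`, `fitted`.
#' @export
sine_regression <- function(bin_means, a_tol = 1e-8) {
  y <- as.numeric(bin_means)
  x <- seq_along(y)
  flat_fit <- function() {
    structure(
      list(a = 0, f = 1, phi = 0, c = mean(y), sse = sum((y - mean(y))^2),
           r2 = 0, flat = TRUE, fitted = rep(mean(y), length(y))),
      class = "sine_fit"
    )
  }
  if (sd(y) < 1e-12) return(flat_fit())
  sse_of <- function(p) {
    sum((y - (p[1] * sin(p[2] * x * pi / 3 + p[3]) + p[4]))^2)
  }
  best <- NULL
  a0 <- (max(y) - min(y)) / 2
  for (f0 in c(0.5, 1, 2)) {
    for (phi0 in c(0, pi / 2, pi, 3 * pi / 2)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ a * sin(f * x * pi / 3 + phi) + c0,
          start = list(a = a0, f = f0, phi = phi0, c0 = mean(y)),
          lower = c(a = -Inf, f = 0.25, phi = -Inf, c0 = -Inf),
          upper = c(a = Inf, f = 3, phi = Inf, c0 = Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      p <- coef(fit)
      s <- sse_of(p)
      if (is.null(best) || s < best$sse) {
        best <- list(p = p, sse = s)
      }
    }
  }
  if (is.null(best)) return(flat_fit())
  p <- best$p
  a <- p[["a"]]; f <- p[["f"]]; phi <- p[["phi"]]; c0 <- p[["c0"]]
  # canonical form: a >= 0, f >= 0, phi in [0, 2*pi)
  if (f < 0) {
    f <- -f; phi <- -phi; a <- -a
  }
  if (a < 0) {
    a <- -a; phi <- phi + pi
  }
  phi <- phi %% (2 * pi)
  if (a < a_tol) return(flat_fit())
  fitted <- a * sin(f * x * pi / 3 + phi) + c0
  sst <- sum((y - mean(y))^2)
  structure(
    list(a = a, f = f, phi = phi, c = c0, sse = best$sse,
         r2 = 1 - best$sse / sst, flat = FALSE, fitted = fitted),
    class = "sine_fit"
  )
}

#' @export
print.sine_fit <- function(x, ...) {
  cat(sprintf(
    "<sine_fit> y = %.4g * sin(%.4g * x * pi/3 + %.4g) + %.4g  (R2 = %.3f%s)\n",
    x$a, x$f, x$phi, x$c, x$r2, if (x$flat) ", flat" else ""
  ))
  invisible(x)
}

#' One-way repeated-measures ANOVA over phase bins
#'
#' Within-subject ANOVA with bin as the single factor. Degrees of freedom are
#' `(bins - 1, (bins - 1) * (participants - 1))`.
#'
#' @param data Either a participants x bins numeric matrix, or a long tibble
#'   with columns `participant`, `bin`, `value`. The table must be complete
#'   (no missing cells).
#' @return A one-row tibble: `df1`, `df2`, `F`, `p`.
#' @export
rm_anova_bins <- function(data) {
  if (is.data.frame(data)) {
    wide <- tidyr::pivot_wider(
      data[, c("participant", "bin", "value")],
      names_from = "bin", values_from = "value"
    )
    m <- as.matrix(wide[, -1])
  } else {
    m <- as.matrix(data)
  }
  if (anyNA(m)) stop_bad_arg("rm_anova_bins requires a complete table")
  n <- nrow(m); b <- ncol(m)
  grand <- mean(m)
  ss_bin <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- b * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_bin - ss_subj
  df1 <- b - 1
  df2 <- (b - 1) * (n - 1)
  if (ss_bin < 1e-12 && ss_err < 1e-12) {
    # degenerate: every participant flat across bins
    return(tibble::tibble(df1 = df1, df2 = df2, F = 0, p = 1))
  }
  f_stat <- (ss_bin / df1) / (ss_err / df2)
  tibble::tibble(df1 = df1, df2 = df2, F = f_stat,
                 p = stats::pf(f_stat, df1, df2, lower.tail = FALSE))
}

#' Correlate IAF with entrained ITPC
#'
#' Pearson correlations (two-tailed) of per-participant post-entrainment
#' ITPC with (a) the individual alpha frequency itself and (b) the absolute
#' distance between IAF and the 10 Hz entraining frequency.
#'
#' @param data Tibble with columns `iaf` (Hz) and `itpc` (per-participant
#'   mean over the entrained windows at 10 Hz), at least 3 rows.
#' @param stim_freq Entraining frequency in Hz (default 10).
#' @return A tibble with one row per predictor: `predictor`, `n`, `r`, `p`.
#' @export
correlate_iaf_itpc <- function(data, stim_freq = 10) {
  if (nrow(data) < 3) stop_bad_arg("need at least 3 participants")
  if (sd(data$itpc) == 0 || sd(data$iaf) == 0) {
    stop_bad_arg("zero variance makes the correlation undefined")
  }
  preds <- list(iaf = data$iaf, iaf_distance = abs(data$iaf - stim_freq))
  purrr::map_dfr(names(preds), function(nm) {
    x <- preds[[nm]]
    if (sd(x) == 0) stop_bad_arg("zero variance makes the correlation undefined")
    ct <- cor.test(x, data$itpc)
    tibble::tibble(predictor = nm, n = nrow(data), r = unname(ct$estimate),
                   p = ct$p.value)
  })
}
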