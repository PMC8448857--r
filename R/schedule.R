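#' Build a balanced blocked trial schedule
#'
#' The experimental design is 2 (rhythmicity: rhythmic / arrhythmic) x
#' 2 (stimulation: active / sham) within-subject. Rhythmicity is blocked:
#' half the blocks are rhythmic and half arrhythmic (order seeded). Within
#' each block, stimulation type and target side are balanced in equal-count
#' cells and the trial order is randomized. The default full design is 8
#' blocks of 64 trials (512 trials, 128 per rhythmicity x stimulation cell).
#'
#' Each trial carries its four pulse onset times (ms relative to pre-cue
#' onset at t = 0): pulse 1 at 105 ms and pulse 4 at 405 ms in every
#' condition; rhythmic gaps are exactly 100 ms; arrhythmic trials have pulses
#' 2-3 jittered by the bimodal mixture `0.5 N(+30, 10) + 0.5 N(-30, 10)` ms,
#' jointly resampled until all gaps are at least 20 ms.
#'
#' @param n_blocks Even number of blocks.
#' @param trials_per_block Number of trials per block, divisible by 4.
#' @param seed Integer seed; the schedule is a deterministic function of
#'   `(n_blocks, trials_per_block, seed)`.
#' @return A tibble with one row per trial: `block`, `trial`, `rhythmicity`,
#'   `stimulation`, `target_side`, and pulse onsets `p1`..`p4` in ms.
#' @examples
#' sched <- make_trial_schedule(2, 8, seed = 1)
#' dplyr::count(sched, rhythmicity, stimulation)
#' @export
make_trial_schedule <- function(n_blocks = 8, trials_per_block = 64, seed) {
  if (n_blocks < 2 || n_blocks %% 2 != 0) {
    stop_bad_arg("n_blocks must be even (half rhythmic, half arrhythmic)")
  }
  if (trials_per_block %% 4 != 0) {
    stop_bad_arg("trials_per_block must be divisible by 4 (2 x 2 balanced cells)")
  }
  seeds <- child_seeds(seed, n_blocks + 1)
  rhythm <- with_seed(
    seeds[1],
    sample(rep(c("rhythmic", "arrhythmic"), n_blocks / 2))
  )
  blocks <- lapply(seq_len(n_blocks), function(b) {
    cell <- tidyr::expand_grid(
      stimulation = c("active", "sham"),
      target_side = c("left", "right")
    )
    trials <- cell[rep(seq_len(4), each = trials_per_block / 4), ]
    bseeds <- child_seeds(seeds[b + 1], 2)
    trials <- trials[with_seed(bseeds[1], sample(nrow(trials))), ]
    pt <- pulse_trains(nrow(trials), rhythm[b], seed = bseeds[2])
    dplyr::bind_cols(
      tibble::tibble(
        block = b,
        trial = seq_len(nrow(trials)),
        rhythmicity = rhythm[b]
      ),
      trials, pt
    )
  })
  out <- dplyr::bind_rows(blocks)
  out$trial <- seq_len(nrow(out))
  out
}

#' Draw arrhythmic jitter offsets for pulses 2 and 3
#'
#' Offsets are drawn independently from the equal-weight bimodal mixture
#' `0.5 N(+30, 10) + 0.5 N(-30, 10)` (ms) and jointly resampled until the
#' resulting train 105, 205 + j2, 305 + j3, 405 ms is strictly increasing
#' with every inter-pulse gap at least `min_gap` ms (which keeps the 14 ms
#' artifact-interpolation windows non-overlapping).
#'
#' @param n Number of offset pairs to draw.
#' @param seed Integer seed.
#' @param min_gap Minimum inter-pulse gap in ms (default 20).
#' @return A tibble with columns `j2`, `j3` in ms, `n` rows.
#' @examples
#' j <- sample_arrhythmic_jitter(1000, seed = 1)
#' mean(abs(j$j2)) # close to 30 ms
#' @export
sample_arrhythmic_jitter <- function(n = 1, seed, min_gap = 20) {
  with_seed(seed, {
    draw <- function(m) {
      sign <- sample(c(-30, 30), m, replace = TRUE)
      sign + rnorm(m, 0, 10)
    }
    j2 <- draw(n)
    j3 <- draw(n)
    for (attempt in seq_len(1000)) {
      p <- cbind(105, 205 + j2, 305 + j3, 405)
      bad <- (p[, 2] - p[, 1] < min_gap) | (p[, 3] - p[, 2] < min_gap) |
        (p[, 4] - p[, 3] < min_gap)
      if (!any(bad)) break
      j2[bad] <- draw(sum(bad))
      j3[bad] <- draw(sum(bad))
    }
    if (any(bad)) {
      abort("failed to draw admissible jitter after 1000 attempts")
    }
    tibble::tibble(j2 = j2, j3 = j3)
  })
}

#' Four-pulse train onsets for a set of trials
#'
#' @param n Number of trials.
#' @param rhythmicity "rhythmic" (gaps exactly 100 ms) or "arrhythmic"
#'   (pulses 2-3 jittered; see [sample_arrhythmic_jitter()]).
#' @param seed Integer seed (used only for arrhythmic trains).
#' @return A tibble with columns `p1`..`p4` (ms relative to pre-cue onset).
#' @export
pulse_trains <- function(n, rhythmicity = c("rhythmic", "arrhythmic"), seed = NULL) {
  rhythmicity <- match.arg(rhythmicity)
  if (rhythmicity == "rhythmic") {
    return(tibble::tibble(
      p1 = rep(105, n), p2 = rep(205, n), p3 = rep(305, n), p4 = rep(405, n)
    ))
  }
  j <- sample_arrhythmic_jitter(n, seed = seed)
  tibble::tibble(p1 = 105, p2 = 205 + j$j2, p3 = 305 + j$j3, p4 = 405)
}
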