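# bind complex trial x channel x freq x time arrays along the trial axis
abind_trials <- function(arrs) {
  d1 <- vapply(arrs, function(a) dim(a)[1], 0L)
  rest <- dim(arrs[[1]])[-1]
  out <- array(0i, c(sum(d1), rest))
  at <- 0
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , , ] <- a
    at <- at + dim(a)[1]
  }
  dimnames(out) <- c(list(NULL), dimnames(arrs[[1]])[-1])
  out
}

#' Cohort-level phase-bin analysis
#'
#' Runs the pre-TMS phase dependence analysis on a simulated cohort: for each
#' participant, the rhythmic-active trials are wavelet-transformed at the
#' target frequency, each trial's pre-TMS phase (10 Hz, 200 ms before the
#' first pulse) assigns it to one of six circular bins, and ITPC is computed
#' within bin per time sample of the post-entrainment window. Bin means are
#' taken over the participant x time samples (per-participant ITPC first,
#' then averaged), and a sinusoidal regression is fitted to the six means.
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param f Target frequency in Hz (default 10).
#' @param window Analysis window in ms, endpoints inclusive (default
#'   `c(205, 705)`).
#' @param n_bins Number of phase bins (default 6).
#' @param origin Lower edge of the first bin in radians (default `-pi`).
#' @param channels Channels of interest (default `c("O2", "PO4")`).
#' @param rhythmicity,stimulation Condition cell analysed (defaults
#'   "rhythmic", "active").
#' @param pool If `TRUE`, ITPC is computed over the trials of all
#'   participants pooled (one ITPC per bin and time point, `participant`
#'   recorded as `NA`); the default computes ITPC within participant first
#'   and averages across participants, which respects the repeated-measures
#'   structure.
#' @return An object of class `phase_bin_result`: `samples` (tibble of
#'   participant x bin x time ITPC), `means` (per-bin mean, SEM, n), `fit`
#'   (a [sine_regression()] object), `anova` (from [rm_anova_bins()], NULL
#'   if any participant-bin cell is missing), and the bin edges.
#' @export
phase_bin_cohort <- function(cohort, f = 10, window = c(205, 705), n_bins = 6,
                             origin = -pi, channels = c("O2", "PO4"),
                             rhythmicity = "rhythmic", stimulation = "active",
                             pool = FALSE) {
  bank <- wavelet_bank(freqs = f)
  per_part <- lapply(seq_len(nrow(cohort)), function(i) {
    ep <- cohort$epochs[[i]]
    sel <- ep$info$rhythmicity == rhythmicity &
      ep$info$stimulation == stimulation
    sub <- epochs_subset(ep, sel)
    tf <- wavelet_transform(sub, bank)
    phases <- pre_tms_phase(tf, f = f, channels = channels)
    list(tf = tf, phases = phases)
  })
  samples <- if (pool) {
    # pooled variant: one ITPC per bin x time over all participants' trials
    dat <- abind_trials(lapply(per_part, function(p) p$tf$data))
    tf1 <- per_part[[1]]$tf
    tf_all <- tf_map(dat, tf1$freqs, tf1$times, tf1$ch_names, "complex",
                     tf1$valid)
    phases <- unlist(lapply(per_part, function(p) p$phases))
    dplyr::mutate(
      phase_bin_itpc(tf_all, phases, window = window, f = f, n_bins = n_bins,
                     origin = origin, channels = channels),
      participant = NA_integer_, .before = 1
    )
  } else {
    purrr::map_dfr(seq_along(per_part), function(i) {
      dplyr::mutate(
        phase_bin_itpc(per_part[[i]]$tf, per_part[[i]]$phases,
                       window = window, f = f, n_bins = n_bins,
                       origin = origin, channels = channels),
        participant = cohort$participant[i], .before = 1
      )
    })
  }
  means <- dplyr::summarise(
    dplyr::group_by(samples, .data$bin),
    mean = mean(.data$itpc, na.rm = TRUE),
    sem = sd(.data$itpc, na.rm = TRUE) / sqrt(sum(!is.na(.data$itpc))),
    n = sum(!is.na(.data$itpc)),
    .groups = "drop"
  )
  fit <- sine_regression(means$mean)
  anova <- if (pool) {
    NULL # no repeated-measures structure once trials are pooled
  } else {
    pp <- dplyr::summarise(
      dplyr::group_by(samples, .data$participant, .data$bin),
      value = mean(.data$itpc), .groups = "drop"
    )
    if (anyNA(pp$value)) NULL else rm_anova_bins(pp)
  }
  edges <- origin + 2 * pi * (0:n_bins) / n_bins
  structure(
    list(samples = samples, means = means, fit = fit, anova = anova,
         edges = edges, f = f, window = window),
    class = "phase_bin_result"
  )
}

#' @export
print.phase_bin_result <- function(x, ...) {
  cat(sprintf(
    "<phase_bin_result> %d bins at %g Hz over [%g, %g] ms\n",
    nrow(x$means), x$f, x$window[1], x$window[2]
  ))
  print(x$means)
  print(x$fit)
  if (!is.null(x$anova)) {
    cat(sprintf("RM-ANOVA: F(%d, %d) = %.2f, p = %.3g\n",
                x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  }
  invisible(x)
}
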