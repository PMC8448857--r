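#' Run the end-to-end analysis pipeline
#'
#' Executes every stage on synthetic data: cohort simulation (schedules,
#' phase-resetting oscillators, artifacts), preprocessing (interpolation,
#' downsampling, epoching), the phase-locked signatures (evoked amplitude and
#' ITPC at the target frequency), planned window contrasts, a topographic
#' cluster permutation test in the configured window, the pre-TMS phase-bin
#' analysis with sinusoidal regression, per-participant IAF estimation with
#' the IAF-ITPC correlation, and the psychophysics stage (simulated observer,
#' Naka-Rushton fit, contrast titration). Results are returned as tidy
#' tables and, if `out_dir` is given, written as CSV/JSON files whose bytes
#' depend only on (config, seed).
#'
#' With fewer than 3 participants the inferential columns (t, p, r) are
#' reported as NA; the tables keep their shape.
#'
#' @param config Configuration list (see [default_config()] /
#'   [read_run_config()]).
#' @param out_dir Optional output directory (created if missing).
#' @return Invisibly, a list: `cohort_iaf`, `metrics`, `contrasts`,
#'   `cluster`, `phase_bins`, `iaf_correlation`, `behavior`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(!is.null(config$seed))
  seeds <- child_seeds(config$seed, 4)
  montage <- montage_1020(config$preprocess$n_channels)

  cohort <- simulate_cohort(
    n_participants = config$design$n_participants,
    kappa = config$model$kappa,
    n_blocks = config$design$n_blocks,
    trials_per_block = config$design$trials_per_block,
    montage = montage,
    fs = config$preprocess$fs,
    target_fs = config$preprocess$target_fs,
    seed = seeds[1],
    iaf_sd = config$model$iaf_sd,
    alpha_amp = config$model$alpha_amp,
    noise_amp = config$model$noise_amp,
    artifact_amp = config$model$artifact_amp,
    artifact_duration = config$model$artifact_duration
  )
  n_part <- nrow(cohort)

  metrics <- window_metrics(
    cohort, f = config$analysis$f, channels = config$analysis$channels
  )
  contrasts <- if (n_part >= 3) {
    planned_contrasts(metrics)
  } else {
    act <- metrics[metrics$stimulation == "active", ]
    diffs <- tidyr::pivot_wider(
      tidyr::pivot_longer(act, c("itpc", "evoked"), names_to = "measure"),
      names_from = "rhythmicity", values_from = "value"
    )
    dplyr::summarise(
      dplyr::group_by(diffs, .data$measure, .data$window),
      n = dplyr::n(), mean_diff = mean(.data$rhythmic - .data$arrhythmic),
      t = NA_real_, df = NA_real_, p = NA_real_, .groups = "drop"
    )
  }

  # topographies: per-participant window-mean ITPC at f, all channels
  cl_win <- analysis_windows()
  cl_win <- cl_win[cl_win$window == config$analysis$cluster_window, ]
  bank <- wavelet_bank(freqs = config$analysis$f)
  topo_of <- function(ep, rhythmicity) {
    sub <- epochs_subset(
      ep, ep$info$rhythmicity == rhythmicity & ep$info$stimulation == "active"
    )
    pc <- itpc(wavelet_transform(sub, bank))
    tsel <- pc$valid[1, ] & pc$times >= cl_win$start & pc$times < cl_win$end
    rowMeans(matrix(pc$data[, 1, tsel], nrow = length(pc$ch_names)))
  }
  topo_r <- t(vapply(cohort$epochs, topo_of, numeric(nrow(montage)), "rhythmic"))
  topo_a <- t(vapply(cohort$epochs, topo_of, numeric(nrow(montage)), "arrhythmic"))
  colnames(topo_r) <- colnames(topo_a) <- montage$channel
  cluster <- if (n_part >= 3) {
    cluster_permutation(
      topo_r, topo_a, channel_adjacency(montage),
      n_perm = config$analysis$n_perm, tail = "one", seed = seeds[2]
    )
  } else {
    NULL
  }

  phase_bins <- phase_bin_cohort(
    cohort, f = config$analysis$f, n_bins = config$analysis$n_bins,
    channels = config$analysis$channels
  )

  rest_seeds <- child_seeds(seeds[3], n_part)
  iaf_est <- vapply(seq_len(n_part), function(i) {
    estimate_iaf(simulate_rest(cohort$model[[i]], duration = 120,
                               seed = rest_seeds[i]))
  }, 0.0)
  entrained <- dplyr::summarise(
    dplyr::group_by(
      metrics[metrics$stimulation == "active" &
                metrics$rhythmicity == "rhythmic" &
                metrics$window %in% paste0("W", 2:6), ],
      .data$participant
    ),
    itpc = mean(.data$itpc), .groups = "drop"
  )
  iaf_tbl <- tibble::tibble(
    participant = cohort$participant, iaf_true = cohort$iaf, iaf = iaf_est,
    itpc = entrained$itpc[match(cohort$participant, entrained$participant)]
  )
  iaf_correlation <- if (n_part >= 3 && sd(iaf_tbl$iaf) > 0 &&
                           sd(iaf_tbl$itpc) > 0) {
    dplyr::bind_cols(
      correlate_iaf_itpc(iaf_tbl, stim_freq = config$analysis$f)
    )
  } else {
    tibble::tibble(predictor = c("iaf", "iaf_distance"), n = n_part,
                   r = NA_real_, p = NA_real_)
  }

  beh_cfg <- config$behavior
  beh_seeds <- child_seeds(seeds[4], length(beh_cfg$contrasts))
  beh <- purrr::map_dfr(seq_along(beh_cfg$contrasts), function(i) {
    resp <- simulate_observer(
      beh_cfg$contrasts[i],
      list(dmax = beh_cfg$dmax, c50 = beh_cfg$c50, n = beh_cfg$n),
      n_trials = beh_cfg$trials_per_level, seed = beh_seeds[i]
    )
    cnt <- sdt_counts(resp)
    dplyr::mutate(
      dprime_criterion(cnt$hits, cnt$misses, cnt$fas, cnt$crs),
      contrast = beh_cfg$contrasts[i], .before = 1
    )
  })
  nr_fit <- fit_naka_rushton(beh$contrast, beh$dprime)
  behavior <- list(
    by_contrast = beh, fit = nr_fit,
    c50 = nr_fit$c50,
    titrated_contrast = if (nr_fit$converged &&
                              beh_cfg$target_dprime < nr_fit$dmax) {
      titrate_contrast(nr_fit, beh_cfg$target_dprime)
    } else {
      NA_real_
    }
  )

  result <- list(
    cohort_iaf = iaf_tbl, metrics = metrics, contrasts = contrasts,
    cluster = cluster, phase_bins = phase_bins,
    iaf_correlation = iaf_correlation, behavior = behavior, config = config
  )
  if (!is.null(out_dir)) write_report(result, out_dir)
  invisible(result)
}

# write the tidy result tables; output bytes depend only on (config, seed)
write_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(result$contrasts, "window_contrasts.csv")
  wcsv(result$metrics, "window_metrics.csv")
  wcsv(result$cohort_iaf, "participants.csv")
  wcsv(result$phase_bins$means, "phase_bin_means.csv")
  wcsv(result$behavior$by_contrast, "behavior_by_contrast.csv")
  if (!is.null(result$cluster)) {
    wcsv(tidy(result$cluster), "cluster_test.csv")
  }
  summary <- list(
    seed = result$config$seed,
    package_version = as.character(utils::packageVersion("entrainr")),
    sine_fit = glance(result$phase_bins$fit),
    rm_anova = result$phase_bins$anova,
    iaf_correlation = result$iaf_correlation,
    naka_rushton = tidy(result$behavior$fit),
    titrated_contrast = result$behavior$titrated_contrast
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
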