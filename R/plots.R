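#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_point
#'   geom_errorbar geom_hline labs scale_fill_viridis_c theme_minimal
#'   facet_wrap geom_text coord_fixed
#' @export
ggplot2::autoplot

#' Plot a time-frequency map
#'
#' Raster of amplitude or ITPC over time and frequency, averaged over the
#' requested channels; edge-flagged samples are blanked.
#'
#' @param object A real [tf_map()] (evoked amplitude or ITPC).
#' @param channels Channels to average (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tf_map <- function(object, channels = NULL, ...) {
  df <- tidy(object)
  if (object$quantity == "complex") {
    df <- dplyr::summarise(
      dplyr::group_by(df, .data$channel, .data$freq, .data$time, .data$valid),
      value = mean(.data$value), .groups = "drop"
    )
  }
  if (!is.null(channels)) df <- df[df$channel %in% channels, ]
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$freq, .data$time, .data$valid),
    value = mean(.data$value), .groups = "drop"
  )
  df$value[!df$valid] <- NA
  ggplot(df, aes(x = .data$time, y = .data$freq, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = object$quantity, na.value = "grey90") +
    labs(x = "time (ms)", y = "frequency (Hz)") +
    theme_minimal()
}

#' Plot a phase-bin ITPC result
#'
#' Bin means with SEM error bars and the fitted sinusoid evaluated on a fine
#' grid.
#'
#' @param object A `phase_bin_result` from [phase_bin_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_bin_result <- function(object, ...) {
  m <- object$means
  xg <- seq(0.5, nrow(m) + 0.5, length.out = 200)
  curve <- tibble::tibble(
    bin = xg,
    itpc = object$fit$a * sin(object$fit$f * xg * pi / 3 + object$fit$phi) +
      object$fit$c
  )
  ggplot(m, aes(x = .data$bin, y = .data$mean)) +
    geom_line(data = curve, aes(y = .data$itpc), colour = "steelblue") +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem), width = 0.15) +
    geom_point(size = 2) +
    labs(x = "pre-TMS phase bin", y = "ITPC") +
    theme_minimal()
}

#' Plot a cluster permutation test topography
#'
#' Channel-wise t-values on the layout, with members of significant clusters
#' highlighted.
#'
#' @param object A `cluster_test` from [cluster_permutation()].
#' @param layout Electrode layout from [montage_1020()] matching the tested
#'   channels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_test <- function(object, layout, ...) {
  df <- dplyr::left_join(
    layout, tibble::tibble(channel = names(object$t_obs), t = object$t_obs),
    by = "channel"
  )
  sig <- unique(unlist(object$clusters$channels[object$clusters$significant]))
  df$significant <- df$channel %in% sig
  ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_point(aes(colour = .data$t, size = .data$significant)) +
    geom_text(aes(label = .data$channel), vjust = -1, size = 2.5) +
    ggplot2::scale_colour_gradient2(low = "navy", high = "firebrick") +
    ggplot2::scale_size_manual(values = c(`FALSE` = 2, `TRUE` = 4)) +
    coord_fixed() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot a Naka-Rushton fit
#'
#' Measured sensitivities and the fitted contrast-response curve on a log
#' contrast axis, with the c50 point marked.
#'
#' @param object A `naka_rushton_fit` from [fit_naka_rushton()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.naka_rushton_fit <- function(object, ...) {
  pts <- tibble::tibble(contrast = object$contrasts, dprime = object$dprimes)
  cg <- exp(seq(log(min(object$contrasts)), log(max(object$contrasts)),
                length.out = 200))
  curve <- tibble::tibble(contrast = cg, dprime = predict(object, cg))
  ggplot(pts, aes(x = .data$contrast, y = .data$dprime)) +
    geom_line(data = curve, colour = "steelblue") +
    geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$c50, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    labs(x = "contrast", y = "d'") +
    theme_minimal()
}
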