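#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a time-frequency map into a long tibble
#'
#' @param x A [tf_map()].
#' @param ... Unused.
#' @return A tibble with columns `channel`, `freq`, `time`, `valid` and
#'   `value` (modulus for complex maps, with an extra `phase` column), one
#'   row per (trial x) channel x frequency x time point; complex per-trial
#'   maps also carry a `trial` column.
#' @export
tidy.tf_map <- function(x, ...) {
  d <- dim(x$data)
  if (length(d) == 4) {
    grid <- tidyr::expand_grid(
      time_i = seq_along(x$times), freq_i = seq_along(x$freqs),
      channel = x$ch_names, trial = seq_len(d[1])
    )
    vals <- as.vector(x$data)
    out <- tibble::tibble(
      trial = grid$trial,
      channel = grid$channel,
      freq = x$freqs[grid$freq_i],
      time = x$times[grid$time_i],
      value = Mod(vals),
      phase = Arg(vals),
      valid = as.vector(x$valid[cbind(grid$freq_i, grid$time_i)])
    )
  } else {
    grid <- tidyr::expand_grid(
      time_i = seq_along(x$times), freq_i = seq_along(x$freqs),
      channel = x$ch_names
    )
    out <- tibble::tibble(
      channel = grid$channel,
      freq = x$freqs[grid$freq_i],
      time = x$times[grid$time_i],
      value = as.vector(x$data),
      valid = as.vector(x$valid[cbind(grid$freq_i, grid$time_i)])
    )
  }
  out
}

#' Tidy the cluster table of a cluster permutation test
#'
#' @param x A `cluster_test` object from [cluster_permutation()].
#' @param ... Unused.
#' @return The cluster tibble with channels as comma-separated strings.
#' @export
tidy.cluster_test <- function(x, ...) {
  dplyr::mutate(
    x$clusters,
    channels = vapply(.data$channels, paste, "", collapse = ",")
  )
}

#' @export
glance.cluster_test <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    min_p = if (nrow(x$clusters)) min(x$clusters$p) else NA_real_,
    threshold = x$threshold, tail = x$tail, n_perm = x$n_perm
  )
}

#' @export
tidy.sine_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "f", "phi", "c"),
    estimate = c(x$a, x$f, x$phi, x$c)
  )
}

#' @export
glance.sine_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, r.squared = x$r2, flat = x$flat)
}

#' @export
tidy.naka_rushton_fit <- function(x, ...) {
  tibble::tibble(
    term = c("dmax", "c50", "n"),
    estimate = c(x$dmax, x$c50, x$n)
  )
}

#' @export
glance.naka_rushton_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, converged = x$converged,
                 n_levels = length(x$contrasts))
}

#' @export
tidy.phase_bin_result <- function(x, ...) x$means

#' @export
glance.phase_bin_result <- function(x, ...) {
  out <- tibble::tibble(
    a = x$fit$a, f = x$fit$f, phi = x$fit$phi, c = x$fit$c,
    r.squared = x$fit$r2, flat = x$fit$flat
  )
  if (!is.null(x$anova)) {
    out <- dplyr::bind_cols(out, dplyr::rename(x$anova, F_bins = "F"))
  }
  out
}
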