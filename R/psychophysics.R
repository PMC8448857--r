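#' Signal-detection sensitivity and criterion
#'
#' Computes `d' = z(H) - z(FA)` and criterion `c = -(z(H) + z(FA)) / 2` from
#' trial counts. When any observed rate is 0 or 1 (and `correction =
#' "auto"`), the log-linear correction is applied: 0.5 is added to every cell
#' and 1 to each denominator, keeping both quantiles finite.
#'
#' @param hits,misses,fas,crs Trial counts (hits/misses on signal trials,
#'   false alarms/correct rejections on noise trials). Each class (signal and
#'   noise) must contain at least one trial.
#' @param correction `"auto"` (apply when a rate is extreme; default),
#'   `"always"`, or `"never"`.
#' @return A one-row tibble: `dprime`, `criterion`, `hit_rate`, `fa_rate`.
#' @examples
#' dprime_criterion(69, 31, 31, 69) # d' ~ 0.99, c ~ 0
#' @export
dprime_criterion <- function(hits, misses, fas, crs,
                             correction = c("auto", "always", "never")) {
  correction <- match.arg(correction)
  n_sig <- hits + misses
  n_noise <- fas + crs
  if (n_sig < 1 || n_noise < 1) {
    stop_bad_arg("each class needs at least one trial")
  }
  h <- hits / n_sig
  fa <- fas / n_noise
  extreme <- h %in% c(0, 1) || fa %in% c(0, 1)
  if (correction == "always" || (correction == "auto" && extreme)) {
    h <- (hits + 0.5) / (n_sig + 1)
    fa <- (fas + 0.5) / (n_noise + 1)
  }
  zh <- qnorm(h)
  zf <- qnorm(fa)
  tibble::tibble(
    dprime = zh - zf, criterion = -(zh + zf) / 2, hit_rate = h, fa_rate = fa
  )
}

#' Tabulate an observer's response table into SDT counts
#'
#' Treats "cw" as the signal class: hits are cw responses to cw signals,
#' false alarms cw responses to ccw signals.
#'
#' @param responses Tibble from [simulate_observer()] (columns `signal`,
#'   `response`).
#' @return A one-row tibble of counts: `hits`, `misses`, `fas`, `crs`.
#' @export
sdt_counts <- function(responses) {
  tibble::tibble(
    hits = sum(responses$signal == "cw" & responses$response == "cw"),
    misses = sum(responses$signal == "cw" & responses$response == "ccw"),
    fas = sum(responses$signal == "ccw" & responses$response == "cw"),
    crs = sum(responses$signal == "ccw" & responses$response == "ccw")
  )
}

# Naka-Rushton contrast-response function
naka_rushton <- function(contrast, dmax, c50, n) {
  dmax * contrast^n / (contrast^n + c50^n)
}

#' Fit a Naka-Rushton contrast-response function
#'
#' Least-squares fit of `d'(c) = dmax * c^n / (c^n + c50^n)` to sensitivity
#' measured at several contrasts (the method of constant stimuli used 4-80%
#' contrast in 7 log steps). The fit is performed in log-contrast space,
#' where the function is a logistic in `log(c)` - numerically better
#' conditioned - with multi-start over the exponent `n in {1, 2, 3}`. By
#' definition `d'(c50) = dmax / 2`.
#'
#' @param contrasts Contrast levels as proportions in (0, 1]; at least 4.
#' @param dprimes Measured sensitivity at each contrast.
#' @return An object of class `naka_rushton_fit`: `dmax`, `c50`, `n`, `sse`,
#'   `converged`, plus the data.
#' @export
fit_naka_rushton <- function(contrasts, dprimes) {
  if (length(contrasts) < 4) stop_bad_arg("need at least 4 contrast levels")
  stopifnot(length(contrasts) == length(dprimes), all(contrasts > 0))
  lc <- log(contrasts)
  y <- dprimes
  best <- NULL
  for (n0 in c(1, 2, 3)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ dmax / (1 + exp(-n * (lc - lc50))),
        start = list(dmax = max(y), n = n0, lc50 = median(lc)),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    s <- sum(residuals(fit)^2)
    if (is.null(best) || s < best$sse) best <- list(fit = fit, sse = s)
  }
  if (is.null(best)) {
    return(structure(
      list(dmax = NA_real_, c50 = NA_real_, n = NA_real_, sse = NA_real_,
           converged = FALSE, contrasts = contrasts, dprimes = dprimes),
      class = "naka_rushton_fit"
    ))
  }
  p <- coef(best$fit)
  structure(
    list(dmax = unname(p["dmax"]), c50 = unname(exp(p["lc50"])),
         n = unname(p["n"]), sse = best$sse, converged = TRUE,
         contrasts = contrasts, dprimes = dprimes),
    class = "naka_rushton_fit"
  )
}

#' @export
print.naka_rushton_fit <- function(x, ...) {
  cat(sprintf(
    "<naka_rushton_fit> dmax = %.3f, c50 = %.3f, n = %.3f (SSE %.3g%s)\n",
    x$dmax, x$c50, x$n, x$sse, if (x$converged) "" else ", NOT converged"
  ))
  invisible(x)
}

#' @export
predict.naka_rushton_fit <- function(object, contrasts, ...) {
  naka_rushton(contrasts, object$dmax, object$c50, object$n)
}

#' Invert a fitted contrast-response function
#'
#' Returns the contrast at which the fitted Naka-Rushton curve reaches a
#' target sensitivity (the titration used to run the main task at d' ~ 1.2).
#'
#' @param fit A [fit_naka_rushton()] object.
#' @param target_dprime Target sensitivity (default 1.2).
#' @return Contrast as a proportion; NA (with a warning) if the target
#'   exceeds the fitted asymptote.
#' @export
titrate_contrast <- function(fit, target_dprime = 1.2) {
  if (!fit$converged) stop_bad_arg("cannot titrate from an unconverged fit")
  if (target_dprime >= fit$dmax) {
    warn("target sensitivity exceeds the fitted asymptote")
    return(NA_real_)
  }
  fit$c50 * (target_dprime / (fit$dmax - target_dprime))^(1 / fit$n)
}
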