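#' Single-component cosinor fit
#'
#' Fits the rhythmometric model
#' \deqn{Y(t) = M + A \cos\left(\frac{2\pi (t - \phi)}{\tau}\right) + e(t)}
#' by ordinary least squares on cosine/sine regressors, where `M` is the
#' MESOR (rhythm-adjusted mean), `A >= 0` the amplitude (half the
#' peak-to-trough range of the fitted cosine) and `phi` the acrophase, the
#' clock time of the fitted peak. The zero-amplitude test is the classical
#' F statistic on 2 numerator degrees of freedom comparing the cosinor fit
#' against the flat model.
#'
#' When the fitted amplitude is numerically zero
#' (`A < 1e-9 * max(|M|, 1)`) the acrophase is undefined and reported as
#' `NA` with `undefined_acrophase = TRUE`.
#'
#' @param series an [epoch_series()], or any object with numeric fields
#'   `time` (hours) and `value` when calling the workhorse
#'   [cosinor_lm()] directly.
#' @param period_h rhythm period in hours (default 24).
#' @param log_transform if `TRUE`, fit on `log10(x + 1)` transformed
#'   values (off by default; reported MESOR/amplitude are then on the
#'   transformed scale).
#'
#' @return An object of class `cosinor`: a list with elements `mesor`,
#'   `amplitude`, `acrophase_h` (clock hours in `[0, 24)`), `rss`,
#'   `f_zero_amp`, `p_zero_amp`, `n_used`, `undefined_acrophase` and
#'   `period_h`.
#' @examples
#' t <- seq(0, 24 * 7 - 1 / 60, by = 1 / 60)
#' y <- 10 + 5 * cos(2 * pi * (t - 14) / 24)
#' fit_cosinor(epoch_series(y))
#' @seealso [nonparametric_metrics()], [normalized_amplitude()]
#' @export
fit_cosinor <- function(series, period_h = 24, log_transform = FALSE) {
  stopifnot(inherits(series, "epoch_series"))
  t <- series$start_h + time_hours(series)
  y <- series$values
  if (log_transform) y <- log10(y + 1)
  cosinor_lm(t, y, period_h = period_h)
}

#' @describeIn fit_cosinor least-squares cosinor on arbitrary (possibly
#'   irregular) time points; `time_h` in hours, need not be sorted.
#' @param time_h numeric vector of sampling times in hours.
#' @param values numeric vector of measurements, same length as `time_h`.
#' @export
cosinor_lm <- function(time_h, values, period_h = 24) {
  ok <- is.finite(time_h) & is.finite(values)
  t <- time_h[ok]
  y <- values[ok]
  n <- length(y)
  if (n < 3L || length(unique(t)) < 3L)
    stop("cosinor fit needs at least 3 distinct non-missing time points")
  if (diff(range(t)) <= period_h / 2)
    stop("degenerate time support: samples must span more than half a period")
  w <- 2 * pi / period_h
  X <- cbind(1, cos(w * t), sin(w * t))
  fit <- .lm.fit(X, y)
  if (fit$rank < 3L)
    stop("degenerate time support: cosinor design is rank deficient")
  b <- fit$coefficients
  mesor <- b[1]
  amplitude <- sqrt(b[2]^2 + b[3]^2)
  rss <- sum(fit$residuals^2)
  rss0 <- sum((y - mean(y))^2)
  tol <- 1e-9 * max(abs(mesor), 1)
  undef <- amplitude < tol
  acro <- if (undef) NA_real_ else wrap24(atan2(b[3], b[2]) / w)
  if (rss0 <= 1e-12 * max(1, mean(y)^2)) {
    f <- 0
    p <- 1
  } else {
    ms_res <- rss / (n - 3)
    f <- if (ms_res <= 0) Inf else ((rss0 - rss) / 2) / ms_res
    p <- stats::pf(f, 2, n - 3, lower.tail = FALSE)
  }
  structure(
    list(mesor = mesor, amplitude = amplitude, acrophase_h = acro,
         rss = rss, f_zero_amp = f, p_zero_amp = p, n_used = n,
         undefined_acrophase = undef, period_h = period_h),
    class = "cosinor"
  )
}

#' @export
print.cosinor <- function(x, ...) {
  acro <- if (x$undefined_acrophase) "undefined"
          else sprintf("%02d:%02d", floor(x$acrophase_h),
                       round((x$acrophase_h %% 1) * 60))
  cat(sprintf(
    "<cosinor %gh> MESOR %.4g  amplitude %.4g  acrophase %s  F(2,%d) %.3g  p %.3g\n",
    x$period_h, x$mesor, x$amplitude, acro, x$n_used - 3,
    x$f_zero_amp, x$p_zero_amp))
  invisible(x)
}

#' Normalized amplitude (amplitude-to-MESOR ratio)
#'
#' The amplitude of a fitted cosinor divided by its MESOR; applied to the
#' blue light channel this is the "NA BLE" circadian light hygiene index.
#' Large values indicate a strong day/night contrast in exposure; small
#' values indicate weak daytime light, irregular patterns, or light at
#' night.
#'
#' @param cosinor a [fit_cosinor()] result.
#' @return a non-negative scalar.
#' @export
normalized_amplitude <- function(cosinor) {
  stopifnot(inherits(cosinor, "cosinor"))
  if (!is.finite(cosinor$mesor) || cosinor$mesor <= 0)
    stop("normalized amplitude is undefined for MESOR <= 0")
  cosinor$amplitude / cosinor$mesor
}

#' Circular mean of clock times
#'
#' Angular mean of clock hours on the 24 h circle, as needed to summarise
#' acrophases and window onsets that straddle midnight. The mean is
#' undefined (zero resultant) for perfectly symmetric inputs.
#'
#' @param times_h numeric vector of clock hours.
#' @return list with `mean_h` (in `[0, 24)`, `NA` if undefined) and
#'   `resultant` (mean resultant length in `[0, 1]`, a dispersion measure:
#'   1 = all times identical).
#' @examples
#' circular_mean_clock(c(23.5, 0.5)) # wraps to midnight
#' @export
circular_mean_clock <- function(times_h) {
  if (length(times_h) == 0L) stop("empty list of clock times")
  th <- 2 * pi * times_h / 24
  cbar <- mean(cos(th))
  sbar <- mean(sin(th))
  r <- sqrt(cbar^2 + sbar^2)
  mean_h <- if (r < 1e-9) NA_real_ else wrap24(atan2(sbar, cbar) * 24 / (2 * pi))
  list(mean_h = mean_h, resultant = r)
}

#' Linearize clock-time variables for regression
#'
#' Clock-valued predictors (acrophases, M10/L5 onsets) live on a circle;
#' nocturnal onsets near midnight straddle 0 h, which would wreck a naive
#' linear treatment. Values are unwrapped to a continuous scale centered on
#' the circular mean: each time is mapped to `mean + d`, with `d` the signed
#' circular difference in `(-12, 12]` hours.
#'
#' @param times_h clock hours; `NA` passed through.
#' @param center optional fixed center (clock hours); defaults to the
#'   circular mean of the non-missing values.
#' @return numeric vector on a linear hour scale.
#' @export
unwrap_clock <- function(times_h, center = NULL) {
  ok <- is.finite(times_h)
  if (!any(ok)) return(times_h)
  if (is.null(center)) {
    center <- circular_mean_clock(times_h[ok])$mean_h
    if (is.na(center)) center <- 12
  }
  out <- times_h
  out[ok] <- center + circ_diff_h(times_h[ok], center)
  out
}
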