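#' Non-parametric actigraphy light metrics (M10, L5, RA, NA)
#'
#' Computes the non-parametric circadian endpoints of a per-minute light
#' series on its composite day (per-clock-minute mean across days):
#'
#' * `m10` / `m10_onset_h` — mean over the 10 most-exposed consecutive
#'   hours (600-minute cyclic window) and the clock time of the window
#'   start;
#' * `l5` / `l5_onset_h` — mean over the 5 least-exposed consecutive hours
#'   (300-minute window);
#' * `ra` — relative amplitude `(M10 - L5) / (M10 + L5)`, in `[0, 1]`;
#' * `na` — normalized amplitude, the paired cosinor's amplitude/MESOR
#'   ratio (see [normalized_amplitude()]).
#'
#' Windows are searched at 1-minute resolution over all 1440 cyclic start
#' positions; ties are broken by the earliest clock onset. With
#' `basis = "per_day"` the windows are instead located within each retained
#' day and the per-day levels averaged (onsets averaged circularly).
#'
#' @param series an [epoch_series()] covering at least one full day.
#' @param cosinor optional matching [fit_cosinor()] estimate; fitted from
#'   `series` when omitted. Used only for `na`.
#' @param basis `"composite"` (default) or `"per_day"`.
#' @param max_missing_frac per-day missingness tolerance passed to
#'   [composite_day()].
#' @return An object of class `np_metrics`: list with `m10`, `m10_onset_h`,
#'   `l5`, `l5_onset_h`, `ra`, `na`.
#' @examples
#' sq <- rep(c(rep(0, 480), rep(100, 720), rep(0, 240)), 2)
#' nonparametric_metrics(epoch_series(sq))
#' @export
nonparametric_metrics <- function(series, cosinor = NULL,
                                  basis = c("composite", "per_day"),
                                  max_missing_frac = 0.2) {
  basis <- match.arg(basis)
  stopifnot(inherits(series, "epoch_series"))
  if (is.null(cosinor)) cosinor <- fit_cosinor(series)
  stopifnot(inherits(cosinor, "cosinor"))

  if (basis == "composite") {
    comp <- composite_day(series, max_missing_frac = max_missing_frac)
    m10w <- best_window(comp, 600L, which = "max")
    l5w <- best_window(comp, 300L, which = "min")
  } else {
    days <- split_days(series, max_missing_frac)
    m10s <- lapply(days, best_window, width = 600L, which = "max")
    l5s <- lapply(days, best_window, width = 300L, which = "min")
    m10w <- list(level = mean(vapply(m10s, `[[`, 0, "level")),
                 onset_h = circular_mean_clock(
                   vapply(m10s, `[[`, 0, "onset_h"))$mean_h)
    l5w <- list(level = mean(vapply(l5s, `[[`, 0, "level")),
                onset_h = circular_mean_clock(
                  vapply(l5s, `[[`, 0, "onset_h"))$mean_h)
  }

  tot <- m10w$level + l5w$level
  ra <- if (tot > 0) (m10w$level - l5w$level) / tot else NA_real_
  na_val <- tryCatch(normalized_amplitude(cosinor), error = function(e) {
    warning(conditionMessage(e), call. = FALSE)
    NA_real_
  })
  structure(
    list(m10 = m10w$level, m10_onset_h = m10w$onset_h,
         l5 = l5w$level, l5_onset_h = l5w$onset_h,
         ra = ra, na = na_val),
    class = "np_metrics"
  )
}

#' @export
print.np_metrics <- function(x, ...) {
  cat(sprintf(
    "<np_metrics> M10 %.4g @ %05.2fh  L5 %.4g @ %05.2fh  RA %.3f  NA %.3f\n",
    x$m10, x$m10_onset_h, x$l5, x$l5_onset_h, x$ra, x$na))
  invisible(x)
}

# cyclic rolling-window extremum over all 1440 starts, via cumulative sums
# on the doubled day; earliest start wins ties (which.max/min semantics)
best_window <- function(day, width, which = c("max", "min")) {
  which <- match.arg(which)
  stopifnot(length(day) == 1440L)
  xx <- c(day, day[seq_len(width - 1L)])
  cs <- cumsum(c(0, xx))
  means <- (cs[(width + 1):(width + 1440)] - cs[1:1440]) / width
  idx <- if (which == "max") which.max(means) else which.min(means)
  list(level = means[idx], onset_h = (idx - 1) / 60)
}

# clock-aligned days surviving the missingness screen; sparse missing
# minutes (<= the tolerated fraction) are imputed with the day mean so
# window sums stay comparable across starts
split_days <- function(series, max_missing_frac) {
  v <- series$values
  off <- round(series$start_h * 60) %% 1440
  pad <- c(rep(TRUE, off), rep(FALSE, length(v)))
  if (off != 0) v <- c(rep(NA_real_, off), v)
  n_days <- ceiling(length(v) / 1440)
  extra <- n_days * 1440 - length(v)
  v <- c(v, rep(NA_real_, extra))
  pad <- c(pad, rep(TRUE, extra))
  m <- matrix(v, nrow = 1440)
  mp <- matrix(pad, nrow = 1440)
  # per-day windows need whole clock days: truncated edge days are
  # excluded from both the numerator and the requirement
  whole <- colSums(!mp) == 1440L
  keep <- whole & colMeans(is.na(m)) <= max_missing_frac
  need <- min(3L, sum(whole))
  if (need < 1L || sum(keep) < need)
    stop(sprintf("only %d whole days meet the completeness requirement",
                 sum(keep)))
  days <- lapply(which(keep), function(j) {
    d <- m[, j]
    if (anyNA(d)) d[is.na(d)] <- mean(d, na.rm = TRUE)
    d
  })
  days
}
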