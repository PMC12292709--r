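# Correlation rhythmometry: time-resolved correlation between a morning
# lipid value and light exposure in consecutive clock epochs, followed by
# FDR masking and a cosinor fit to the correlation curve r(t).

#' Composite epoch exposure matrix
#'
#' For each recording, the composite-day mean light level in consecutive
#' clock epochs of `epoch_min` minutes: cell `(i, e)` is subject `i`'s
#' mean blue irradiance during clock epoch `e` averaged across the
#' recording's days.
#'
#' @param series_list list of [epoch_series()] (or `light_recording`
#'   objects, whose blue channel is used), one per subject-season row.
#' @param epoch_min epoch width in minutes; must divide 1440 (default 30).
#' @param max_missing_frac per-day completeness bar, see
#'   [composite_day()].
#' @return numeric matrix, rows = recordings, columns = `1440/epoch_min`
#'   epochs, with attribute `"centers_h"` giving epoch center clock hours.
#' @export
epoch_exposure_matrix <- function(series_list, epoch_min = 30,
                                  max_missing_frac = 0.2) {
  if (1440 %% epoch_min != 0)
    stop("epoch_min must divide 1440")
  n_ep <- 1440 %/% epoch_min
  rows <- lapply(series_list, function(s) {
    if (inherits(s, "light_recording")) s <- s$blue
    stopifnot(inherits(s, "epoch_series"))
    comp <- composite_day(s, max_missing_frac = max_missing_frac)
    colMeans(matrix(comp, nrow = epoch_min))
  })
  m <- do.call(rbind, rows)
  attr(m, "centers_h") <- (seq_len(n_ep) - 0.5) * epoch_min / 60
  m
}

#' Epoch-wise correlations of a lipid with exposure
#'
#' Pearson correlation (and two-sided p) of the lipid values with each
#' epoch column of the exposure matrix. Zero-variance epochs yield
#' undefined correlations (`NA`), which are excluded from the BH family
#' and the r-curve cosinor downstream.
#'
#' @param exposure matrix from [epoch_exposure_matrix()].
#' @param lipid numeric vector aligned with the matrix rows.
#' @return list with `r`, `p` (length = number of epochs) and `n`.
#' @export
epochwise_correlation <- function(exposure, lipid) {
  if (nrow(exposure) != length(lipid))
    stop("lipid values are not aligned with the exposure matrix rows")
  if (nrow(exposure) < 4L) stop("need at least 4 rows")
  ok <- is.finite(lipid)
  x <- exposure[ok, , drop = FALSE]
  y <- lipid[ok]
  n <- length(y)
  if (n < 4L) stop("need at least 4 complete rows")
  r <- p <- rep(NA_real_, ncol(x))
  for (e in seq_len(ncol(x))) {
    if (stats::sd(x[, e]) == 0 || stats::sd(y) == 0) next
    ct <- stats::cor.test(x[, e], y)
    r[e] <- unname(ct$estimate)
    p[e] <- ct$p.value
  }
  list(r = r, p = p, n = n)
}

#' Significant-epoch mask after BH correction
#'
#' Delegates to [bh_adjust()] over the per-lipid epoch family (defined
#' epochs only).
#'
#' @param p_values per-epoch p-values (`NA` = undefined epoch).
#' @param fdr FDR level (default 0.1).
#' @return logical mask, `FALSE` wherever `p` is undefined.
#' @export
significant_epoch_mask <- function(p_values, fdr = 0.1) {
  bh_adjust(p_values, fdr)
}

#' Cosinor model of the correlation curve
#'
#' Fits a 24 h single cosinor to the `(epoch center, r)` points by least
#' squares, quantifying the circadian rhythmicity of the time-dependent
#' lipid-light association; the acrophase is the clock time at which the
#' association peaks, and the zero-amplitude F test (df 2, n_epochs - 3)
#' tests the null of no rhythmicity in r(t). Undefined epochs are
#' dropped, not imputed. Correlations are fitted directly; set
#' `fisher_z = TRUE` to fit variance-stabilized `atanh(r)` values
#' instead.
#'
#' @param r_values per-epoch correlations.
#' @param centers_h epoch center clock hours (recycled from the exposure
#'   matrix attribute when a `correlation_rhythm` object is supplied).
#' @param fisher_z fit `atanh(r)` instead of raw r.
#' @return a `cosinor` object.
#' @export
fit_r_rhythm <- function(r_values, centers_h, fisher_z = FALSE) {
  ok <- is.finite(r_values)
  if (sum(ok) < 4L) stop("fewer than 4 defined r-values")
  y <- if (fisher_z) atanh(pmin(pmax(r_values[ok], -1 + 1e-12), 1 - 1e-12))
       else r_values[ok]
  cosinor_lm(centers_h[ok], y)
}

#' Correlation rhythmometry workflow
#'
#' Full epoch-wise workflow for one lipid: exposure matrix column
#' correlations, BH significance mask, and the cosinor model of r(t).
#'
#' @param exposure matrix from [epoch_exposure_matrix()] (with the
#'   `centers_h` attribute) or a list of series to build it from.
#' @param lipid numeric lipid vector aligned to rows.
#' @param epoch_min epoch width when `exposure` is a series list.
#' @param fdr FDR level for the epoch mask.
#' @param fisher_z see [fit_r_rhythm()].
#' @return object of class `correlation_rhythm`: list with
#'   `epoch_centers_h`, `r_values`, `p_values`, `significant_mask`,
#'   `r_cosinor`, `n`.
#' @export
correlation_rhythm <- function(exposure, lipid, epoch_min = 30, fdr = 0.1,
                               fisher_z = FALSE) {
  if (!is.matrix(exposure))
    exposure <- epoch_exposure_matrix(exposure, epoch_min = epoch_min)
  centers <- attr(exposure, "centers_h")
  if (is.null(centers))
    centers <- (seq_len(ncol(exposure)) - 0.5) * 24 / ncol(exposure)
  ec <- epochwise_correlation(exposure, lipid)
  mask <- significant_epoch_mask(ec$p, fdr = fdr)
  fit <- fit_r_rhythm(ec$r, centers, fisher_z = fisher_z)
  structure(list(epoch_centers_h = centers, r_values = ec$r,
                 p_values = ec$p, significant_mask = mask,
                 r_cosinor = fit, n = ec$n),
            class = "correlation_rhythm")
}

#' @export
print.correlation_rhythm <- function(x, ...) {
  cat(sprintf("<correlation_rhythm> %d epochs, n = %d, %d significant\n",
              length(x$r_values), x$n, sum(x$significant_mask)))
  print(x$r_cosinor)
  invisible(x)
}

#' Basic plot of a correlation rhythm
#'
#' Dotted observed r(t), solid fitted cosinor, shaded BH-significant
#' epochs. For inspection only.
#'
#' @param x a [correlation_rhythm()] object.
#' @param ... passed to [plot()].
#' @export
plot.correlation_rhythm <- function(x, ...) {
  ok <- is.finite(x$r_values)
  plot(x$epoch_centers_h[ok], x$r_values[ok], type = "b", lty = 3,
       xlab = "clock time (h)", ylab = "r", xlim = c(0, 24), ...)
  if (any(x$significant_mask)) {
    w <- diff(x$epoch_centers_h[1:2]) / 2
    for (e in which(x$significant_mask))
      polygon(x$epoch_centers_h[e] + c(-w, w, w, -w),
              c(-1, -1, 1, 1), border = NA,
              col = grDevices::adjustcolor("steelblue", 0.15))
  }
  if (!x$r_cosinor$undefined_acrophase) {
    tt <- seq(0, 24, by = 0.1)
    with(x$r_cosinor,
         lines(tt, mesor + amplitude * cos(2 * pi * (tt - acrophase_h) / 24)))
  }
  abline(h = 0, col = "grey")
  invisible(x)
}
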