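#' Salivary melatonin profile
#'
#' One subject-season's 24 h melatonin profile from irregular sampling,
#' typically 21 samples collected over a single day with sampling densest
#' before and during sleep.
#'
#' Times are stored as hours since the start of collection (`time_h`,
#' monotone over the roughly 24 h span) together with the clock hour at
#' which collection started, so acrophases can be reported in clock time.
#'
#' @param time_h hours since start of collection (non-decreasing).
#' @param concentration melatonin concentrations, pg/mL.
#' @param start_clock_h clock hour of the first sample (default 08:00).
#' @param subject,season optional identifiers carried through tables.
#' @return data frame of class `melatonin_profile` with columns `time_h`,
#'   `clock_h`, `concentration`, `valid`.
#' @export
melatonin_profile <- function(time_h, concentration, start_clock_h = 8,
                              subject = NA_character_, season = NA_character_) {
  if (length(time_h) != length(concentration))
    stop("`time_h` and `concentration` lengths differ")
  if (length(time_h) < 2L) stop("a melatonin profile needs at least 2 samples")
  o <- order(time_h)
  time_h <- time_h[o]
  concentration <- concentration[o]
  valid <- is.finite(concentration) & concentration >= 0
  out <- data.frame(
    time_h = time_h,
    clock_h = wrap24(start_clock_h + time_h),
    concentration = concentration,
    valid = valid
  )
  attr(out, "start_clock_h") <- start_clock_h
  attr(out, "subject") <- subject
  attr(out, "season") <- season
  attr(out, "usable") <- sum(valid) >= 4L
  class(out) <- c("melatonin_profile", "data.frame")
  out
}

#' Quality-control filtering of a melatonin profile
#'
#' Removes invalid entries (non-finite or negative concentrations) and
#' extreme outliers, defined as changes greater than 2 standard deviations
#' between consecutive samples. The SD is computed once over all
#' consecutive differences of the raw (validity-screened) profile, and
#' samples are flagged in a single deterministic pass: each sample is
#' compared against its most recent *accepted* predecessor and removed when
#' the step exceeds `2 * SD`. The threshold is stored with the profile, so
#' filtering an already-filtered profile reuses it and is a no-op
#' (idempotence).
#'
#' @param profile a [melatonin_profile()].
#' @param k outlier multiplier (default 2 SDs).
#' @return the profile with outliers marked invalid and a `qc` attribute:
#'   list with `threshold` and a `removals` audit data frame
#'   (`time_h`, `concentration`, `reason`).
#' @export
qc_filter <- function(profile, k = 2) {
  stopifnot(inherits(profile, "melatonin_profile"))
  if (nrow(profile) < 2L) stop("QC needs at least 2 samples")

  removals <- data.frame(time_h = numeric(), concentration = numeric(),
                         reason = character())
  bad <- !(is.finite(profile$concentration) & profile$concentration >= 0)
  if (any(bad & profile$valid)) {
    removals <- rbind(removals, data.frame(
      time_h = profile$time_h[bad & profile$valid],
      concentration = profile$concentration[bad & profile$valid],
      reason = "invalid value"))
  }
  profile$valid[bad] <- FALSE

  qc_prev <- attr(profile, "qc")
  if (!is.null(qc_prev)) {
    thr <- qc_prev$threshold
  } else {
    conc <- profile$concentration[profile$valid]
    if (length(conc) < 3L) thr <- Inf
    else {
      s <- stats::sd(diff(conc))
      thr <- if (is.finite(s) && s > 0) k * s else Inf
    }
  }

  idx <- which(profile$valid)
  if (length(idx) >= 2L && is.finite(thr)) {
    last <- idx[1]
    for (i in idx[-1]) {
      if (abs(profile$concentration[i] - profile$concentration[last]) > thr) {
        profile$valid[i] <- FALSE
        removals <- rbind(removals, data.frame(
          time_h = profile$time_h[i],
          concentration = profile$concentration[i],
          reason = sprintf("jump > %.4g from accepted predecessor", thr)))
      } else {
        last <- i
      }
    }
  }

  prev_removals <- if (!is.null(qc_prev)) qc_prev$removals else
    removals[0, , drop = FALSE]
  attr(profile, "qc") <- list(threshold = thr,
                              removals = rbind(prev_removals, removals))
  attr(profile, "usable") <- sum(profile$valid) >= 4L
  if (!attr(profile, "usable"))
    warning("fewer than 4 samples survive QC: profile marked unusable",
            call. = FALSE)
  profile
}

#' Melatonin acrophase by cosinor on irregular times
#'
#' Fits a single-component 24 h cosinor to a QC-passed profile by least
#' squares on the irregular sampling times and returns the full
#' [cosinor_lm()] estimate; the acrophase is the clock time of peak
#' melatonin.
#'
#' @param profile a [melatonin_profile()], ideally after [qc_filter()].
#' @param period_h rhythm period (default 24 h).
#' @param log_transform fit on `log10(x + 1)` concentrations if `TRUE`
#'   (default fits raw concentrations).
#' @return a `cosinor` object; `acrophase_h` is in clock hours.
#' @export
melatonin_acrophase <- function(profile, period_h = 24, log_transform = FALSE) {
  stopifnot(inherits(profile, "melatonin_profile"))
  ok <- profile$valid
  if (sum(ok) < 4L)
    stop("unusable profile: fewer than 4 valid samples")
  t <- profile$time_h[ok]
  if (diff(range(t)) <= 12)
    stop("samples span <= 12 h: 24 h acrophase would be aliased")
  y <- profile$concentration[ok]
  if (log_transform) y <- log10(y + 1)
  start <- attr(profile, "start_clock_h")
  if (is.null(start) || !is.finite(start)) start <- 0
  cosinor_lm(start + t, y, period_h = period_h)
}
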