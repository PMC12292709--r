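#' Per-minute light exposure series
#'
#' Container for one participant-season's per-minute light recording on a
#' uniform 1-minute grid. Values are non-negative light measurements (lux
#' for the white channel, uW/cm2 for the blue channel); missing minutes are
#' encoded as `NA` and tracked by the missing mask.
#'
#' @param values numeric vector of light readings (`NA` = missing); at
#'   least one full day (1440 minutes) is required.
#' @param start_h clock hour of the first epoch in `[0, 24)` (default
#'   midnight). Timestamps are naive local clock time; the intended study
#'   region observes no daylight saving time, so no timezone arithmetic is
#'   performed anywhere in the package.
#' @param channel `"blue_irradiance"` or `"white_lux"`.
#' @param step_min sampling step in minutes; only 1 is supported.
#'
#' @return An object of class `epoch_series`.
#' @examples
#' es <- epoch_series(rep(5, 1440))
#' fit_cosinor(es)
#' @export
epoch_series <- function(values, start_h = 0, channel = c("blue_irradiance", "white_lux"),
                         step_min = 1) {
  channel <- match.arg(channel)
  values <- as.numeric(values)
  if (step_min != 1) stop("only 1-minute epochs are supported")
  if (length(values) < 1440L)
    stop("an epoch series must cover at least one full day (1440 minutes)")
  if (any(values < 0, na.rm = TRUE))
    stop("light values must be non-negative")
  if (!is.numeric(start_h) || length(start_h) != 1L || is.na(start_h))
    stop("`start_h` must be a single clock hour")
  structure(
    list(values = values, start_h = wrap24(start_h), step_min = 1,
         channel = channel),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<epoch_series> %s: %d min (%.1f days), start %05.2fh, %d missing\n",
              x$channel, n, n / 1440, x$start_h, sum(is.na(x$values))))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$values)

# hours elapsed since the first sample (monotone, unwrapped)
time_hours <- function(series) {
  (seq_along(series$values) - 1) / 60
}

# clock time of each sample in [0, 24)
clock_hours <- function(series) {
  wrap24(series$start_h + time_hours(series))
}

#' Composite (average) day of a per-minute series
#'
#' Averages the recording per clock minute across days, ignoring missing
#' values. Days in which more than `max_missing_frac` of minutes are missing
#' are dropped entirely before averaging; at least `min(3, n_days)` days
#' must survive. A trailing partial day is padded with missing values.
#'
#' @param series an [epoch_series()].
#' @param max_missing_frac maximum tolerated fraction of missing minutes
#'   per day (default 0.2).
#' @return numeric vector of length 1440, element `i` being the mean value
#'   at clock minute `i - 1` (00:00 first).
#' @export
composite_day <- function(series, max_missing_frac = 0.2) {
  stopifnot(inherits(series, "epoch_series"))
  v <- series$values
  # rotate so index 1 is clock 00:00; the alignment padding is tracked
  # separately from genuine missingness so an off-midnight start does not
  # count against a day's completeness
  off <- round(series$start_h * 60) %% 1440
  pad_head <- rep(TRUE, off)
  pad <- c(pad_head, rep(FALSE, length(v)))
  if (off != 0) v <- c(rep(NA_real_, off), v)
  n_days <- ceiling(length(v) / 1440)
  extra <- n_days * 1440 - length(v)
  v <- c(v, rep(NA_real_, extra))
  pad <- c(pad, rep(TRUE, extra))
  m <- matrix(v, nrow = 1440)
  mp <- matrix(pad, nrow = 1440)
  observed <- colSums(!mp)
  miss_frac <- ifelse(observed > 0,
                      colSums(is.na(m) & !mp) / observed, 1)
  keep <- miss_frac <= max_missing_frac & observed > 0
  need <- min(3L, ncol(m))
  if (sum(keep) < need)
    stop(sprintf("only %d of %d days meet the %.0f%% completeness requirement",
                 sum(keep), ncol(m), 100 * (1 - max_missing_frac)))
  m <- m[, keep, drop = FALSE]
  comp <- rowMeans(m, na.rm = TRUE)
  if (any(!is.finite(comp)))
    stop("composite day has undefined minutes (no data at some clock times)")
  comp
}
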