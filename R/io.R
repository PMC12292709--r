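# Readers and writers for the documented per-minute CSV dialect and the
# pipeline's TSV tables. Timestamps are naive local clock time written as
# ISO-8601 (the study region observes no daylight saving time); all float
# output is rounded to 6 significant digits.

#' Write a light recording to the per-minute CSV dialect
#'
#' Columns: `timestamp` (ISO-8601 local, 1-minute grid), `lux`,
#' `blue_uw_cm2`, `activity`. Missing minutes are written with empty
#' light fields.
#'
#' @param recording a `light_recording` (see [generate_light_series()]).
#' @param path output file.
#' @param start_date date of the first sample (the recording's
#'   `start_h` sets the time of day).
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(recording, path, start_date = "2024-01-01") {
  stopifnot(inherits(recording, "light_recording"))
  n <- length(recording$blue$values)
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC") +
    round(recording$blue$start_h * 3600)
  ts <- t0 + 60 * (seq_len(n) - 1)
  df <- data.frame(
    timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"),
    lux = fmt_signif(recording$white$values),
    blue_uw_cm2 = fmt_signif(recording$blue$values),
    activity = recording$activity
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a per-minute light CSV
#'
#' Parses the documented dialect (`timestamp`, `lux`, `blue_uw_cm2`,
#' `activity`), enforcing a 1-minute grid: gaps are filled as missing
#' minutes (with a warning), duplicate timestamps are an error, and
#' malformed rows are skipped with a warning up to a 1% tolerance, beyond
#' which reading aborts.
#'
#' @param path CSV file.
#' @return a `light_recording` with `blue` and `white` [epoch_series()]
#'   and the `activity` vector.
#' @export
read_epoch_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "lux", "blue_uw_cm2", "activity")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  ts <- as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  lux <- suppressWarnings(as.numeric(raw$lux))
  blue <- suppressWarnings(as.numeric(raw$blue_uw_cm2))
  act <- suppressWarnings(as.numeric(raw$activity))
  # a row is malformed if its timestamp cannot be parsed or a present
  # light value is not numeric (empty fields mean "missing", not bad)
  bad <- is.na(ts) |
    (!is.na(raw$blue_uw_cm2) & nzchar(trimws(raw$blue_uw_cm2)) & is.na(blue)) |
    (!is.na(raw$lux) & nzchar(trimws(raw$lux)) & is.na(lux))
  if (any(bad)) {
    if (mean(bad) > 0.01)
      stop(sprintf("%d malformed rows (> 1%% of file): aborting", sum(bad)))
    warning(sprintf("skipped %d malformed row(s)", sum(bad)), call. = FALSE)
    ts <- ts[!bad]; lux <- lux[!bad]; blue <- blue[!bad]; act <- act[!bad]
  }
  if (length(ts) < 2L) stop("no usable rows in ", path)
  if (anyDuplicated(ts)) {
    dup <- format(ts[duplicated(ts)][1], "%Y-%m-%dT%H:%M:%S")
    stop("duplicate timestamp: ", dup)
  }
  o <- order(ts)
  ts <- ts[o]; lux <- lux[o]; blue <- blue[o]; act <- act[o]
  grid <- seq(ts[1], ts[length(ts)], by = 60)
  idx <- match(as.numeric(grid), as.numeric(ts))
  if (any(as.numeric(ts) %% 60 != as.numeric(ts[1]) %% 60))
    stop("timestamps are not on a 1-minute grid")
  n_gap <- sum(is.na(idx))
  if (n_gap > 0)
    warning(sprintf("%d missing minute(s) filled as NA", n_gap),
            call. = FALSE)
  blue_g <- blue[idx]; lux_g <- lux[idx]
  act_g <- act[idx]
  start_h <- as.numeric(format(grid[1], "%H")) +
    as.numeric(format(grid[1], "%M")) / 60
  structure(
    list(blue = epoch_series(blue_g, start_h = start_h,
                             channel = "blue_irradiance"),
         white = epoch_series(lux_g, start_h = start_h,
                              channel = "white_lux"),
         activity = act_g, season = NA_character_, params = NULL),
    class = "light_recording")
}

# fixed-column-order TSV writers/readers used by every stage
write_tsv <- function(df, path) {
  df[] <- lapply(df, fmt_signif)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  read.csv(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Default pipeline configuration
#'
#' All tunables of the end-to-end pipeline in one nested list; can be
#' serialized to/from YAML ([read_config()]).
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    n_subjects = 27,
    seasons = c("WS", "SE", "SS"),
    synth = list(noise_sigma = 0.6, dip = 0.3, lux_factor = 7,
                 melatonin_fraction = 13 / 27),
    metrics = list(basis = "composite", log_transform = FALSE),
    stats = list(fdr = 0.1, family = "all", vif_ceiling = 5),
    rhythm = list(epoch_min = 30, fisher_z = FALSE)
  )
}

#' Read and validate a YAML pipeline configuration
#'
#' Unspecified fields fall back to [default_config()] values; the merged
#' configuration is validated before any computation.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    user <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, user)
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$stats$fdr) || cfg$stats$fdr <= 0 || cfg$stats$fdr >= 1)
    stop("config error: stats.fdr must lie in (0, 1)")
  if (!is.numeric(cfg$seed) || cfg$seed < 0)
    stop("config error: seed must be a non-negative integer")
  if (cfg$n_subjects < 2)
    stop("config error: n_subjects must be at least 2")
  if (!all(cfg$seasons %in% c("WS", "SE", "SS")))
    stop("config error: seasons must be among WS, SE, SS")
  if (1440 %% cfg$rhythm$epoch_min != 0)
    stop("config error: rhythm.epoch_min must divide 1440")
  if (!cfg$metrics$basis %in% c("composite", "per_day"))
    stop("config error: metrics.basis must be composite or per_day")
  if (!cfg$stats$family %in% c("all", "per_outcome"))
    stop("config error: stats.family must be all or per_outcome")
  invisible(cfg)
}
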