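#' Sampling schedule for a synthetic melatonin profile
#'
#' Collection times for a 24 h saliva series starting at `start_clock_h`,
#' densest before and during sleep: 70% of samples are placed evenly
#' (with optional jitter) in the 21:00-08:00 window and the remainder
#' through the daytime. The exact 21 collection times of the emulated
#' protocol are not published; this template honours its density
#' constraint and is fully configurable.
#'
#' @param n_samples number of samples (default 21, minimum 4).
#' @param start_clock_h clock hour at which collection starts.
#' @param jitter_h half-width of the uniform jitter applied to each time
#'   (0 disables; jitter uses the current RNG stream).
#' @return numeric vector of hours since collection start, sorted,
#'   within `[0, 24)`.
#' @export
melatonin_schedule <- function(n_samples = 21, start_clock_h = 8,
                               jitter_h = 0) {
  if (n_samples < 4) stop("n_samples < 4: cosinor would be unidentifiable")
  n_night <- ceiling(0.7 * n_samples)
  n_day <- n_samples - n_night
  # clock positions on a day running start..start+24; the dense block
  # spans 20:30 through 08:15 of the next morning so it covers both steep
  # flanks of a nocturnal peak, and the sparse daytime samples are spaced
  # to track the flatter trough (closer together where the profile still
  # changes, wider apart around mid-afternoon)
  night <- seq(20.5, 32.25, length.out = n_night)
  day_template <- c(9.25, 10.75, 12.5, 14.5, 16.75, 19)
  day <- if (n_day >= 2) {
    stats::approx(seq(0, 1, length.out = length(day_template)),
                  day_template, xout = seq(0, 1, length.out = n_day))$y
  } else if (n_day == 1) 14 else numeric()
  clock <- c(day, night)
  if (jitter_h > 0)
    clock <- clock + stats::runif(length(clock), -jitter_h, jitter_h)
  since_start <- clock - start_clock_h
  sort(pmin(pmax(since_start, 0.01), 23.99))
}

#' Generate a synthetic salivary melatonin profile
#'
#' Cosine-shaped melatonin concentrations sampled on an irregular 24 h
#' schedule dense at night, with additive Gaussian noise floored at zero.
#'
#' @param acrophase_h clock hour of peak melatonin.
#' @param mesor,amplitude cosine mesor and amplitude in pg/mL; the
#'   amplitude must not exceed the mesor so expected concentrations stay
#'   non-negative.
#' @param n_samples number of samples (default 21).
#' @param noise_sd additive noise SD in pg/mL.
#' @param seed non-negative integer seed.
#' @param start_clock_h nominal collection start (clock hours) for a
#'   03:30 peak; the actual start shifts with `acrophase_h`, emulating
#'   schedules personalized from sleep diaries.
#' @param jitter_h schedule jitter half-width in hours.
#' @param subject,season identifiers carried into the profile.
#' @return a [melatonin_profile()].
#' @examples
#' p <- generate_melatonin_profile(3.5, mesor = 12, amplitude = 10,
#'                                 noise_sd = 0, seed = 1)
#' melatonin_acrophase(p)$acrophase_h
#' @export
generate_melatonin_profile <- function(acrophase_h, mesor, amplitude,
                                       n_samples = 21, noise_sd = 2, seed = 0,
                                       start_clock_h = 8, jitter_h = 0.25,
                                       subject = NA_character_,
                                       season = NA_character_) {
  if (amplitude > mesor)
    stop("amplitude must not exceed mesor (expected concentrations >= 0)")
  if (n_samples < 4) stop("n_samples < 4: cosinor would be unidentifiable")
  with_seed(seed, {
    # personalized schedule: the template is laid out for a 03:30 peak;
    # the whole collection window is shifted by the subject's phase,
    # mirroring protocols that build collection times from each
    # participant's sleep diary
    time_h <- melatonin_schedule(n_samples, 8, jitter_h)
    start_clock_h <- wrap24(start_clock_h + circ_diff_h(acrophase_h, 3.5))
    clock <- start_clock_h + time_h
    mu <- mesor + amplitude * cos(2 * pi * (clock - acrophase_h) / 24)
    conc <- pmax(mu + stats::rnorm(n_samples, 0, noise_sd), 0)
    melatonin_profile(time_h, conc, start_clock_h = start_clock_h,
                      subject = subject, season = season)
  })
}
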