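# Light-series generation: each subject-season is a daytime exposure
# plateau (artificial light widens the effective bright window well beyond
# the natural photoperiod) over a weakly modulated nocturnal baseline,
# with multiplicative log-normal minute noise.

# Width and height of a rectangular bright window whose 24 h cosinor has
# the requested MESOR and fundamental amplitude over baseline `b`:
#   mesor = b + h * W / 24
#   amplitude = (2 h / pi) * sin(pi * W / 24)
# so W solves x / (2 sin x) = (mesor - b) / amplitude with x = pi W / 24,
# a strictly increasing map from (0, pi) onto (1/2, Inf).
solve_window <- function(mesor, amplitude, baseline) {
  if (amplitude <= 0) return(list(width_h = 0, height = 0))
  ratio <- (mesor - baseline) / amplitude
  ratio <- min(max(ratio, 0.505), 10)
  x <- stats::uniroot(function(x) x / (2 * sin(x)) - ratio,
                      lower = 1e-6, upper = pi - 1e-6, tol = 1e-10)$root
  list(width_h = 24 * x / pi, height = pi * amplitude / (2 * sin(x)))
}

# trapezoid window indicator on clock hours `t`: 1 inside
# [center - width/2, center + width/2] (cyclic), with linear ramps of
# total duration `ramp_h` centered on each edge (mean-preserving)
window_indicator <- function(t, center, width_h, ramp_h = 0.5) {
  if (width_h <= 0) return(numeric(length(t)))
  half <- width_h / 2
  d <- abs(circ_diff_h(t, center))
  if (ramp_h <= 0) return(as.numeric(d <= half))
  pmin(1, pmax(0, (half + ramp_h / 2 - d) / ramp_h))
}

# fraction by which a centered 5 h window mean dips below the baseline
# level at the trough of the nocturnal cosine modulation, per unit dip
l5_dip_factor <- function(dip, window_h = 5) {
  u <- pi * window_h / 24
  dip * sin(u) / u
}

# per-subject draws from a season profile (latent "true" endpoints)
draw_season_params <- function(profile, n, dip = 0.3,
                               acro_offset = 0, na_offset = 0) {
  validate_profile(profile)
  mesor <- rlnorm_ms(n, profile$mesor_mean, profile$mesor_sd)
  na <- stats::rnorm(n, profile$na_mean, profile$na_sd) + na_offset
  na <- pmin(pmax(na, 0.05), 1.85)
  acro <- wrap24(stats::rnorm(n, profile$acrophase_mean_h,
                              profile$acrophase_sd_h) + acro_offset)
  lan <- rlnorm_ms(n, profile$lan_mean, profile$lan_sd)
  lan_onset <- wrap24(stats::rnorm(n, profile$lan_onset_mean_h,
                                   profile$lan_onset_sd_h))
  # baseline level reproducing the L5 target under the trough modulation,
  # capped so the bright window stays solvable (see solve_window)
  baseline <- lan / (1 - l5_dip_factor(dip))
  cap <- 0.9 * mesor * pmax(1 - 0.51 * na, 0.02)
  baseline <- pmin(baseline, cap)
  data.frame(mesor = mesor, na = na, amplitude = na * mesor,
             acrophase_h = acro, lan = lan, lan_onset_h = lan_onset,
             baseline = baseline)
}

# deterministic per-minute waveform (clock hours t) for one draw;
# the plateau's fundamental is solved as the target fundamental minus the
# baseline-modulation fundamental, so the planted (MESOR, amplitude,
# acrophase) are recovered exactly by a noiseless cosinor fit
light_waveform <- function(t, params, dip = 0.3, ramp_h = 0.5) {
  w <- 2 * pi / 24
  trough <- params$lan_onset_h + 2.5
  base <- params$baseline * (1 - dip * cos(w * (t - trough)))
  if (params$amplitude <= 0) {
    return(pmax(base + (params$mesor - params$baseline), 0))
  }
  vec_target <- params$amplitude * exp(1i * w * params$acrophase_h)
  vec_base <- params$baseline * dip * exp(1i * w * (trough + 12))
  vec_plat <- vec_target - vec_base
  geom <- solve_window(params$mesor, Mod(vec_plat), params$baseline)
  center <- wrap24(Arg(vec_plat) / w)
  base + geom$height * window_indicator(t, center, geom$width_h, ramp_h)
}

# closed-form latent non-parametric endpoints implied by a draw's
# geometry; used by the analytic cohort path (no minute series built)
latent_np_metrics <- function(params, dip = 0.3) {
  n <- nrow(params)
  m10 <- m10_onset <- numeric(n)
  for (i in seq_len(n)) {
    p <- params[i, ]
    geom <- solve_window(p$mesor, p$amplitude, p$baseline)
    wdt <- geom$width_h
    m10[i] <- p$baseline + geom$height * min(wdt, 10) / 10
    m10_onset[i] <- if (wdt >= 10) wrap24(p$acrophase_h - wdt / 2)
                    else wrap24(p$acrophase_h + wdt / 2 - 10)
  }
  l5 <- params$baseline * (1 - l5_dip_factor(dip))
  data.frame(m10 = m10, m10_onset_h = m10_onset,
             l5 = l5, l5_onset_h = params$lan_onset_h,
             ra = (m10 - l5) / (m10 + l5),
             na = params$na)
}

#' Generate a synthetic per-minute light recording
#'
#' Simulates one participant-season's 7-day wearable recording: a daytime
#' blue-light plateau (bright-window width and height solved so a cosinor
#' fit recovers the drawn MESOR, amplitude and acrophase), a nocturnal
#' baseline whose 5 h minimum matches the drawn light-at-night level with
#' a shallow trough locating the L5 onset, multiplicative log-normal
#' minute noise, a proportional white-lux channel and a filler activity
#' channel.
#'
#' @param profile one row of [season_profiles()] (or a compatible list).
#' @param seed non-negative integer; identical seeds give bit-identical
#'   recordings.
#' @param days recording length in days (default 7).
#' @param noise_sigma log-scale SD of the multiplicative minute noise
#'   (default 0.6); the noise has unit mean so calibration targets are
#'   preserved in expectation.
#' @param dip fractional depth of the nocturnal baseline trough
#'   (default 0.3).
#' @param ramp_h duration of the linear dawn/dusk ramps in hours.
#' @param lux_factor fixed white-lux to blue-irradiance ratio.
#' @param params optional data frame overriding the random endpoint draw
#'   (columns as in the internal draw: `mesor`, `na`, `amplitude`,
#'   `acrophase_h`, `lan`, `lan_onset_h`, optionally `baseline`).
#' @return An object of class `light_recording`: list with `blue` and
#'   `white` [epoch_series()], integer `activity`, the season label and
#'   the latent `params` actually used.
#' @examples
#' rec <- generate_light_series(season_profiles()["WS", ], seed = 1)
#' fit_cosinor(rec$blue)
#' @export
generate_light_series <- function(profile, seed, days = 7, noise_sigma = 0.6,
                                  dip = 0.3, ramp_h = 0.5, lux_factor = 7,
                                  params = NULL) {
  validate_profile(profile)
  if (days < 1) stop("need at least one day")
  with_seed(seed, {
    if (is.null(params)) {
      params <- draw_season_params(profile, 1L, dip = dip)
    } else {
      params <- as.data.frame(params)
      if (is.null(params$amplitude)) params$amplitude <- params$na * params$mesor
      if (is.null(params$na)) params$na <- params$amplitude / params$mesor
      if (is.null(params$baseline))
        params$baseline <- min(params$lan / (1 - l5_dip_factor(dip)),
                               0.9 * params$mesor * max(1 - 0.51 * params$na, 0.02))
    }
    n <- as.integer(days * 1440)
    t <- (seq_len(n) - 1) / 60 # clock hours from a midnight start
    det <- light_waveform(t, params[1, ], dip = dip, ramp_h = ramp_h)
    noise <- if (noise_sigma > 0)
      exp(noise_sigma * stats::rnorm(n) - noise_sigma^2 / 2) else 1
    blue <- pmax(det * noise, 0)
    day_ind <- window_indicator(wrap24(t), 15.5, 15, ramp_h = 0)
    activity <- stats::rpois(n, 5 + 55 * day_ind)
    structure(
      list(blue = epoch_series(blue, start_h = 0, channel = "blue_irradiance"),
           white = epoch_series(blue * lux_factor, start_h = 0,
                                channel = "white_lux"),
           activity = activity,
           season = profile$season,
           params = params[1, ]),
      class = "light_recording"
    )
  })
}

#' @export
print.light_recording <- function(x, ...) {
  cat(sprintf("<light_recording> season %s, %.1f days\n",
              x$season, length(x$blue$values) / 1440))
  print(x$blue)
  invisible(x)
}
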