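#' Generate a cohort with planted time-of-day lipid-light associations
#'
#' Simulates the scenario probed by correlation rhythmometry: each
#' subject's exposure profile is tilted around the shared daily waveform
#' by two latent phase-preference scores, one peaking at the `hdl` clock
#' time and one at the `tg` clock time, and the two lipids are driven by
#' those scores. The epoch-wise correlation curve `r(t)` between a lipid
#' and exposure then oscillates with its maximum at the planted peak, and
#' the two lipids show the antiphase day/night pattern.
#'
#' Exposure model for subject `i` at clock time `t` (all multiplicative,
#' so values stay positive):
#' `x_i(t) = d(t) * exp(g * (s1_i cos w(t - p1) + s2_i cos w(t - p2)))
#'  * exp(sb * z_ib(t)) * minute noise`,
#' where `d(t)` is the deterministic equinox waveform, `s1, s2` are
#' standard-normal subject scores, and `z_ib` is an independent
#' subject-by-epoch "habit" component constant across days (so it does not
#' average away in the composite day). Lipids are linear in the scores
#' plus noise; with `null = TRUE` the tilt is removed and lipids are pure
#' noise, giving a global-null cohort.
#'
#' @param n_subjects number of subjects.
#' @param peaks named clock hours of the planted association peaks
#'   (defaults: HDL-C morning 08:55, TG near-midnight 23:38).
#' @param strength tilt coefficient `g` (0 disables the association).
#' @param block_sd SD `sb` of the per-epoch habit component.
#' @param lipid_noise SD of the lipid noise relative to the unit-variance
#'   scores.
#' @param epoch_min epoch width in minutes (must divide 1440).
#' @param resolution `"epoch"` generates composite epoch exposures
#'   directly; `"minute"` generates full 7-day per-minute recordings and
#'   is the path the real pipeline takes.
#' @param days recording length for the minute path.
#' @param noise_sigma per-minute log-normal noise SD (minute path).
#' @param null if `TRUE`, sets `strength = 0` (no association).
#' @param seed non-negative integer seed.
#' @return list with `exposure` (`n_subjects` x `1440/epoch_min` composite
#'   epoch matrix), `centers_h` (epoch center clock hours), `lipids`
#'   (data frame `subject`, `hdl`, `tg`), `truth` (the planted peaks), and
#'   for the minute path `recordings` (list of [epoch_series()], blue
#'   channel).
#' @export
generate_rhythm_cohort <- function(n_subjects,
                                   peaks = c(hdl = 8 + 55 / 60,
                                             tg = 23 + 38 / 60),
                                   strength = 0.15, block_sd = 0.45,
                                   lipid_noise = 0.5, epoch_min = 30,
                                   resolution = c("epoch", "minute"),
                                   days = 7, noise_sigma = 0.6,
                                   null = FALSE, seed = 1) {
  resolution <- match.arg(resolution)
  if (1440 %% epoch_min != 0)
    stop("epoch_min must divide 1440")
  stopifnot(all(c("hdl", "tg") %in% names(peaks)))
  if (null) strength <- 0
  n_ep <- 1440 / epoch_min
  w <- 2 * pi / 24

  prof <- season_profiles()["SE", ]
  det_params <- data.frame(
    mesor = prof$mesor_mean, na = prof$na_mean,
    amplitude = prof$na_mean * prof$mesor_mean,
    acrophase_h = prof$acrophase_mean_h, lan = prof$lan_mean,
    lan_onset_h = prof$lan_onset_mean_h,
    baseline = prof$lan_mean / (1 - l5_dip_factor(0.3)))
  t_min <- (seq_len(1440) - 1) / 60
  det_day <- light_waveform(t_min, det_params)
  centers_h <- (seq_len(n_ep) - 0.5) * epoch_min / 60

  with_seed(seed, {
    s1 <- stats::rnorm(n_subjects)
    s2 <- stats::rnorm(n_subjects)
    habit <- matrix(stats::rnorm(n_subjects * n_ep, 0, block_sd),
                    n_subjects, n_ep)
    lipids <- data.frame(
      subject = sprintf("S%03d", seq_len(n_subjects)),
      hdl = 1.4 + 0.35 * (s1 + stats::rnorm(n_subjects, 0, lipid_noise)),
      tg = 1.3 + 0.6 * (s2 + stats::rnorm(n_subjects, 0, lipid_noise)))

    if (resolution == "epoch") {
      det_ep <- colMeans(matrix(det_day, nrow = epoch_min))
      tilt <- outer(s1, cos(w * (centers_h - peaks[["hdl"]]))) +
        outer(s2, cos(w * (centers_h - peaks[["tg"]])))
      exposure <- rep(1, n_subjects) %o% det_ep *
        exp(strength * tilt + habit)
      recordings <- NULL
    } else {
      recordings <- vector("list", n_subjects)
      t_all <- (seq_len(days * 1440) - 1) / 60
      clock <- wrap24(t_all)
      block <- rep(rep(seq_len(n_ep), each = epoch_min), days)
      det_all <- rep(det_day, days)
      tilt1 <- cos(w * (clock - peaks[["hdl"]]))
      tilt2 <- cos(w * (clock - peaks[["tg"]]))
      for (i in seq_len(n_subjects)) {
        y <- det_all *
          exp(strength * (s1[i] * tilt1 + s2[i] * tilt2)) *
          exp(habit[i, block]) *
          exp(noise_sigma * stats::rnorm(length(t_all)) - noise_sigma^2 / 2)
        recordings[[i]] <- epoch_series(y, start_h = 0)
      }
      exposure <- epoch_exposure_matrix(recordings, epoch_min = epoch_min)
    }
    list(exposure = exposure, centers_h = centers_h, lipids = lipids,
         truth = peaks, recordings = recordings)
  })
}
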