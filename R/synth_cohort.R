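#' Generate a synthetic participant-season cohort
#'
#' Simulates the full study design: `n_subjects` participants observed
#' once per season, each subject-season carrying demographics, blue-light
#' exposure metrics, an optional melatonin acrophase, and a fasting lipid
#' panel generated from standardized planted effects.
#'
#' Two generation methods are provided:
#'
#' * `"analytic"` — the light-exposure endpoints are the latent
#'   subject-season draws themselves (closed-form geometry, no minute
#'   series built). Fast; used for large parameter-recovery simulations.
#' * `"series"` — a full 7-day per-minute recording is generated for every
#'   subject-season ([generate_light_series()]) and the endpoints are
#'   estimated from it with [fit_cosinor()] and [nonparametric_metrics()],
#'   exactly as for real recordings. Melatonin acrophases are likewise
#'   fitted from generated 21-sample profiles.
#'
#' Lipids: each latent z-scored log-lipid equals the sum of planted
#' standardized effects over the cohort's realized (z-scored, circularly
#' unwrapped where needed) predictor columns plus Gaussian residual noise
#' scaled so the planted variance ratios hold; concentrations are then
#' mapped log-normally onto the [lipid_reference()] scales. The TG/HDL
#' ratio is always computed as `tg / hdl`, never generated.
#'
#' Each subject keeps persistent latent offsets for acrophase and
#' normalized amplitude across seasons, mimicking stable individual light
#' habits.
#'
#' @param n_subjects number of participants (>= 2).
#' @param profiles data frame of season calibration targets
#'   ([season_profiles()]).
#' @param effects planted standardized effects ([effect_spec()]).
#' @param lipid_ref lipid concentration scales ([lipid_reference()]).
#' @param seed non-negative integer; fixed seeds give byte-identical
#'   cohorts.
#' @param method `"analytic"` or `"series"` (see above).
#' @param seasons season labels to simulate (default all three).
#' @param melatonin_fraction fraction of subjects providing melatonin
#'   profiles (default 13/27 as in the emulated design).
#' @param subject_sd named vector of SDs for the persistent subject
#'   offsets (`acrophase_h` in hours, `na` dimensionless).
#' @param noise_sigma,dip,lux_factor series-generation options passed to
#'   [generate_light_series()].
#' @param keep_recordings if `TRUE` (series method), attach the generated
#'   recordings and melatonin profiles as attributes.
#' @return data frame with one row per subject-season: `subject`, `season`,
#'   `photoperiod_h`, `age`, `sex`, `indigeneity`, `meq`, lipids (`tc`,
#'   `ldl`, `hdl`, `tg`, `tg_hdl`), metrics (`mesor`, `amplitude`,
#'   `acrophase_h`, `m10`, `m10_onset_h`, `l5`, `l5_onset_h`, `ra`, `na`)
#'   and `melatonin_acrophase_h` (`NA` for non-melatonin subjects).
#'   Attribute `"latent"` holds the underlying draws.
#' @examples
#' coh <- generate_cohort(10, seed = 42)
#' head(coh)
#' @export
generate_cohort <- function(n_subjects,
                            profiles = season_profiles(),
                            effects = effect_spec(),
                            lipid_ref = lipid_reference(),
                            seed = 1,
                            method = c("analytic", "series"),
                            seasons = c("WS", "SE", "SS"),
                            melatonin_fraction = 13 / 27,
                            subject_sd = c(acrophase_h = 0.3, na = 0.05),
                            noise_sigma = 0.6, dip = 0.3, lux_factor = 7,
                            keep_recordings = FALSE) {
  method <- match.arg(method)
  if (n_subjects < 2) stop("n_subjects must be at least 2")
  if (!all(seasons %in% profiles$season))
    stop("profiles missing for season(s): ",
         paste(setdiff(seasons, profiles$season), collapse = ", "))
  metric_names <- c("mesor", "amplitude", "acrophase_h", "m10",
                    "m10_onset_h", "l5", "l5_onset_h", "ra", "na")
  validate_effects(effects, metric_names)

  with_seed(seed, {
    subj <- sprintf("S%03d", seq_len(n_subjects))
    demo <- data.frame(
      subject = subj,
      age = sample(18:59, n_subjects, replace = TRUE),
      sex = ifelse(stats::runif(n_subjects) < 0.25, "male", "female"),
      indigeneity = ifelse(stats::runif(n_subjects) < 19 / 27, "NN", "N"),
      meq = sample(45:64, n_subjects, replace = TRUE)
    )
    acro_off <- stats::rnorm(n_subjects, 0, subject_sd[["acrophase_h"]])
    na_off <- stats::rnorm(n_subjects, 0, subject_sd[["na"]])
    mel_off <- stats::rnorm(n_subjects, 0, 0.5)
    n_mel <- round(melatonin_fraction * n_subjects)
    mel_subjects <- sample(subj, n_mel)

    rows <- list()
    for (ss in seasons) {
      prof <- profiles[profiles$season == ss, ]
      pars <- draw_season_params(prof, n_subjects, dip = dip,
                                 acro_offset = acro_off, na_offset = na_off)
      pars$amplitude <- pars$na * pars$mesor
      mel_latent <- wrap24(
        3.5 + 0.6 * circ_diff_h(pars$acrophase_h, prof$acrophase_mean_h) +
          mel_off + stats::rnorm(n_subjects, 0, 0.4))
      rows[[ss]] <- cbind(demo,
                          season = ss, photoperiod_h = prof$photoperiod_h,
                          pars, mel_latent = mel_latent)
    }
    lat <- do.call(rbind, rows)
    rownames(lat) <- NULL
    n_rows <- nrow(lat)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_rows)

    if (method == "analytic") {
      np <- latent_np_metrics(lat, dip = dip)
      met <- cbind(lat[c("mesor", "amplitude", "acrophase_h")], np[-6], na = lat$na)
      mel_fit <- lat$mel_latent
      recordings <- NULL
      mel_profiles <- NULL
    } else {
      recordings <- vector("list", n_rows)
      met <- vector("list", n_rows)
      mel_profiles <- vector("list", n_rows)
      mel_fit <- rep(NA_real_, n_rows)
      for (i in seq_len(n_rows)) {
        prof <- profiles[profiles$season == lat$season[i], ]
        rec <- generate_light_series(prof, seed = sub_seeds[i],
                                     noise_sigma = noise_sigma, dip = dip,
                                     lux_factor = lux_factor,
                                     params = lat[i, c("mesor", "na", "amplitude",
                                                       "acrophase_h", "lan",
                                                       "lan_onset_h", "baseline")])
        cos_fit <- fit_cosinor(rec$blue)
        npm <- nonparametric_metrics(rec$blue, cos_fit)
        met[[i]] <- data.frame(
          mesor = cos_fit$mesor, amplitude = cos_fit$amplitude,
          acrophase_h = cos_fit$acrophase_h,
          m10 = npm$m10, m10_onset_h = npm$m10_onset_h,
          l5 = npm$l5, l5_onset_h = npm$l5_onset_h,
          ra = npm$ra, na = npm$na)
        if (lat$subject[i] %in% mel_subjects) {
          mp <- generate_melatonin_profile(
            lat$mel_latent[i], mesor = 12, amplitude = 10, noise_sd = 2,
            seed = sub_seeds[n_rows + i],
            subject = lat$subject[i], season = lat$season[i])
          mp <- suppressWarnings(qc_filter(mp))
          # a profile can lose too many samples to QC; it is then simply
          # missing, like a failed collection in the field
          mel_fit[i] <- tryCatch(melatonin_acrophase(mp)$acrophase_h,
                                 error = function(e) NA_real_)
          mel_profiles[[i]] <- mp
        }
        recordings[[i]] <- rec
      }
      met <- do.call(rbind, met)
    }

    cohort <- cbind(
      lat[c("subject", "season", "photoperiod_h", "age", "sex",
            "indigeneity", "meq")],
      met)
    cohort$melatonin_acrophase_h <-
      ifelse(cohort$subject %in% mel_subjects,
             if (method == "analytic") lat$mel_latent else mel_fit,
             NA_real_)

    lipids <- plant_lipids(cohort, lat$mel_latent, effects, lipid_ref)
    cohort <- cbind(cohort[1:7], lipids,
                    cohort[setdiff(names(cohort), c(names(cohort)[1:7],
                                                    names(lipids)))])
    attr(cohort, "latent") <- lat
    if (keep_recordings) {
      attr(cohort, "recordings") <- recordings
      attr(cohort, "melatonin_profiles") <- mel_profiles
    }
    cohort
  })
}

# latent z-scored log-lipids from planted standardized effects, mapped
# onto concentration scales; tg_hdl derived, never drawn
plant_lipids <- function(cohort, mel_latent, effects, lipid_ref) {
  n <- nrow(cohort)
  col_for <- function(pred) {
    v <- switch(pred,
                age = cohort$age,
                male = as.numeric(cohort$sex == "male"),
                nn = as.numeric(cohort$indigeneity == "NN"),
                melatonin_acrophase_h = mel_latent,
                cohort[[pred]])
    if (is_circular_name(pred)) v <- unwrap_clock(v)
    s <- stats::sd(v)
    # a degenerate draw (e.g. single-sex tiny cohort) contributes nothing
    if (!is.finite(s) || s == 0) rep(0, n) else (v - mean(v)) / s
  }
  out <- list()
  for (lp in c("tc", "ldl", "hdl", "tg")) {
    eff <- effects[effects$outcome == lp, ]
    y <- numeric(n)
    for (j in seq_len(nrow(eff)))
      y <- y + eff$beta[j] * col_for(eff$predictor[j])
    res_sd <- sqrt(max(0.05, 1 - sum(eff$beta^2)))
    y <- y + stats::rnorm(n, 0, res_sd)
    ref <- lipid_ref[lipid_ref$lipid == lp, ]
    # linear map onto the concentration scale (floored at 5% of the
    # reference mean) so planted standardized effects transfer exactly
    out[[lp]] <- pmax(ref$mean + ref$sd * y, 0.05 * ref$mean)
  }
  out <- as.data.frame(out)
  out$tg_hdl <- out$tg / out$hdl
  out
}
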