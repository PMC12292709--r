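#' Seasonal light-regime calibration profiles
#'
#' Target distributions of blue-light exposure (BLE) endpoints for the
#' three study seasons: winter solstice (WS, photoperiod approximated as
#' 1 h), spring equinox (SE, 12 h) and summer solstice (SS, 23 h). The
#' means and SDs are the published per-season cohort summaries the
#' generator is calibrated to: MESOR and normalized amplitude (with the
#' 24 h amplitude implied as their product), acrophase, the nocturnal
#' baseline level (targeted at the L5 of BLE) and the L5 onset.
#'
#' MESOR and the nocturnal baseline are drawn log-normally (light is
#' non-negative and right-skewed; the summer-solstice SDs exceed the
#' means); normalized amplitude and the clock times are drawn normally,
#' clock times wrapped onto the 24 h circle.
#'
#' @return data frame with one row per season (`WS`, `SE`, `SS`) and
#'   columns `season`, `photoperiod_h`, `mesor_mean`, `mesor_sd`,
#'   `amplitude_mean`, `amplitude_sd` (informational targets),
#'   `acrophase_mean_h`, `acrophase_sd_h`, `na_mean`, `na_sd`, `lan_mean`,
#'   `lan_sd`, `lan_onset_mean_h`, `lan_onset_sd_h`.
#' @export
season_profiles <- function() {
  out <- data.frame(
    season = c("WS", "SE", "SS"),
    photoperiod_h = c(1, 12, 23),
    mesor_mean = c(2.64, 11.11, 36.66),
    mesor_sd = c(1.61, 7.55, 43.81),
    amplitude_mean = c(2.93, 16.12, 49.91),
    amplitude_sd = c(1.74, 11.19, 65.04),
    acrophase_mean_h = c(14.2, 12 + 52 / 60, 14.1),
    acrophase_sd_h = c(1.2, 57 / 60, 1.55),
    na_mean = c(1.12, 1.43, 1.25),
    na_sd = c(0.20, 0.16, 0.29),
    lan_mean = c(0.128, 0.077, 0.816),
    lan_sd = c(0.213, 0.019, 2.871),
    lan_onset_mean_h = c(2 + 4 / 60, 1 + 20 / 60, 1.7),
    lan_onset_sd_h = c(1 + 31 / 60, 1 + 49 / 60, 1 + 19 / 60)
  )
  rownames(out) <- out$season
  out
}

validate_profile <- function(profile) {
  need <- c("season", "photoperiod_h", "mesor_mean", "mesor_sd",
            "acrophase_mean_h", "acrophase_sd_h", "na_mean", "na_sd",
            "lan_mean", "lan_sd", "lan_onset_mean_h", "lan_onset_sd_h")
  miss <- setdiff(need, names(profile))
  if (length(miss))
    stop("season profile is missing fields: ", paste(miss, collapse = ", "))
  if (!profile$season %in% c("WS", "SE", "SS"))
    stop("invalid season label: ", profile$season)
  if (!profile$photoperiod_h %in% c(1, 12, 23))
    stop("photoperiod must be one of 1, 12 or 23 h")
  sds <- unlist(profile[grepl("_sd", need)])
  if (any(sds < 0)) stop("profile SDs must be non-negative")
  if (profile$acrophase_mean_h < 0 || profile$acrophase_mean_h >= 24)
    stop("acrophase mean must lie in [0, 24)")
  invisible(profile)
}

#' Planted standardized lipid effects
#'
#' The generator's effect specification: a table of standardized
#' coefficients mapping light-exposure metrics and demographics onto
#' latent z-scored log-lipid outcomes. The defaults plant the fully
#' adjusted effect sizes reported for this cohort design: nocturnal blue
#' light (L5) raising TC, LDL-C and TG, an earlier blue-light acrophase
#' raising HDL-C, a larger normalized amplitude raising HDL-C and lowering
#' TG, male sex lowering HDL-C, non-native status raising TG, and a later
#' melatonin acrophase raising TG. The TG/HDL ratio is never generated: it
#' is always computed as TG divided by HDL-C, so its associations emerge
#' from the planted TG and HDL-C effects.
#'
#' Clock-valued predictors are standardized on their unwrapped scale
#' (see [unwrap_clock()]). Binary predictors `male` and `nn` are z-scored
#' like any other column.
#'
#' @param null if `TRUE`, return an all-zero specification (pure-noise
#'   lipids), useful for false-discovery checks.
#' @return data frame of class `effect_spec` with columns `outcome`
#'   (`tc`, `ldl`, `hdl`, `tg`), `predictor`, `beta`.
#' @export
effect_spec <- function(null = FALSE) {
  out <- data.frame(
    outcome = c("tc", "tc",
                "ldl", "ldl",
                "hdl", "hdl", "hdl", "hdl",
                "tg", "tg", "tg", "tg", "tg", "tg"),
    predictor = c("l5", "age",
                  "l5", "age",
                  "acrophase_h", "na", "male", "nn",
                  "na", "l5", "l5_onset_h", "nn", "age",
                  "melatonin_acrophase_h"),
    beta = c(0.290, 0.261,
             0.253, 0.244,
             -0.257, 0.241, -0.412, -0.167,
             -0.304, 0.221, 0.246, 0.333, 0.160, 0.30)
  )
  if (null) out$beta <- 0
  class(out) <- c("effect_spec", "data.frame")
  out
}

validate_effects <- function(effects, metric_names) {
  stopifnot(is.data.frame(effects),
            all(c("outcome", "predictor", "beta") %in% names(effects)))
  known <- c(metric_names, "age", "male", "nn", "melatonin_acrophase_h")
  bad <- setdiff(effects$predictor, known)
  if (length(bad))
    stop("unknown predictor(s) in effect spec: ", paste(bad, collapse = ", "))
  if (!all(effects$outcome %in% c("tc", "ldl", "hdl", "tg")))
    stop("effect outcomes must be tc, ldl, hdl or tg (tg_hdl is computed)")
  r2 <- tapply(effects$beta^2, effects$outcome, sum)
  if (any(r2 >= 1))
    stop("planted R-squared >= 1 for outcome(s): ",
         paste(names(r2)[r2 >= 1], collapse = ", "))
  invisible(effects)
}

#' Reference lipid concentration scales
#'
#' Marginal means and SDs used to map latent z-scored outcomes onto
#' concentration units (mmol/L). The source cohort's lipid summary
#' statistics are not published, so these are generic adult reference
#' values — invented defaults, configurable but not calibrated to any
#' cohort. Lipids are mapped log-normally (right-skewed, strictly
#' positive), with moments matched to these means/SDs.
#'
#' @return data frame with columns `lipid`, `mean`, `sd`.
#' @export
lipid_reference <- function() {
  data.frame(
    lipid = c("tc", "ldl", "hdl", "tg"),
    mean = c(5.0, 3.0, 1.4, 1.3),
    sd = c(1.0, 0.9, 0.35, 0.6)
  )
}
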