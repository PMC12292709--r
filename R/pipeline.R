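#' Run the end-to-end analysis pipeline
#'
#' Executes the stages `simulate -> metrics -> melatonin -> associate ->
#' rhythm` against an output directory, writing every table with fixed
#' column order plus a `manifest.json` recording the configuration hash,
#' seed, package and R versions and the MD5 of every artifact. A rerun
#' with the same configuration reproduces all tables byte-identically.
#'
#' Stage artifacts:
#' * `light_<subject>_<season>.csv` — per-minute recordings
#'   ([write_epoch_csv()]); `cohort.tsv` (demographics + lipid panel;
#'   the TG/HDL ratio is never stored, always recomputed);
#'   `melatonin.tsv` (raw melatonin samples).
#' * `metrics.tsv` — per subject-season cosinor and non-parametric
#'   endpoints, per channel.
#' * `melatonin_acrophase.tsv`, `melatonin_qc.tsv` — fitted acrophases
#'   and the QC removal audit.
#' * `table1_correlations.tsv`, `table2_adjusted.tsv`,
#'   `table4_demographics.tsv`, `fig1_matrix.tsv` — the association
#'   battery ([associate_cohort()]).
#' * `rhythm_hdl.tsv`, `rhythm_tg.tsv`, `rhythm_summary.tsv` — the
#'   correlation rhythmometry of the two headline lipids.
#'
#' @param config configuration list ([default_config()]) or path to a
#'   YAML file.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  if (missing(out_dir)) stop("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  season_dates <- c(WS = "2023-12-18", SE = "2024-03-18", SS = "2024-06-17")

  ## --- simulate -----------------------------------------------------
  sim <- stage("simulate", {
    cohort <- generate_cohort(
      config$n_subjects, seed = config$seed, method = "series",
      seasons = config$seasons,
      melatonin_fraction = config$synth$melatonin_fraction,
      noise_sigma = config$synth$noise_sigma, dip = config$synth$dip,
      lux_factor = config$synth$lux_factor, keep_recordings = TRUE)
    recs <- attr(cohort, "recordings")
    mels <- attr(cohort, "melatonin_profiles")
    files <- character(0)
    for (i in seq_len(nrow(cohort))) {
      f <- file.path(out_dir, sprintf("light_%s_%s.csv",
                                      cohort$subject[i], cohort$season[i]))
      write_epoch_csv(recs[[i]], f,
                      start_date = season_dates[[cohort$season[i]]])
      files <- c(files, f)
    }
    cohort_tab <- cohort[c("subject", "season", "photoperiod_h", "age",
                           "sex", "indigeneity", "meq",
                           "tc", "ldl", "hdl", "tg")]
    write_tsv(cohort_tab, file.path(out_dir, "cohort.tsv"))
    mel_tab <- do.call(rbind, lapply(mels[!vapply(mels, is.null, TRUE)],
      function(p) data.frame(subject = attr(p, "subject"),
                             season = attr(p, "season"),
                             time_h = p$time_h, clock_h = p$clock_h,
                             concentration = p$concentration)))
    write_tsv(mel_tab, file.path(out_dir, "melatonin.tsv"))
    list(files = files)
  })

  ## --- metrics (re-read the written CSVs) ---------------------------
  metrics_tab <- stage("metrics", {
    rows <- list()
    for (f in sort(sim$files)) {
      id <- sub("^light_(S[0-9]+)_([A-Z]+)\\.csv$", "\\1:\\2", basename(f))
      rec <- read_epoch_csv(f)
      for (ch in c("blue", "white")) {
        s <- rec[[ch]]
        cf <- fit_cosinor(s, log_transform = config$metrics$log_transform)
        np <- nonparametric_metrics(s, cf, basis = config$metrics$basis)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sub(":.*", "", id), season = sub(".*:", "", id),
          channel = s$channel,
          mesor = cf$mesor, amplitude = cf$amplitude,
          acrophase_h = cf$acrophase_h,
          m10 = np$m10, m10_onset_h = np$m10_onset_h,
          l5 = np$l5, l5_onset_h = np$l5_onset_h,
          ra = np$ra, na = np$na)
      }
    }
    tab <- do.call(rbind, rows)
    write_tsv(tab, file.path(out_dir, "metrics.tsv"))
    tab
  })

  ## --- melatonin ----------------------------------------------------
  mel_acro <- stage("melatonin", {
    mel <- read_tsv(file.path(out_dir, "melatonin.tsv"))
    keys <- unique(mel[c("subject", "season")])
    rows <- list(); audit <- list()
    for (i in seq_len(nrow(keys))) {
      sel <- mel$subject == keys$subject[i] & mel$season == keys$season[i]
      prof <- melatonin_profile(mel$time_h[sel], mel$concentration[sel],
                                start_clock_h = wrap24(mel$clock_h[sel][1] -
                                                       mel$time_h[sel][1]),
                                subject = keys$subject[i],
                                season = keys$season[i])
      prof <- qc_filter(prof)
      qc <- attr(prof, "qc")
      if (nrow(qc$removals))
        audit[[length(audit) + 1L]] <- data.frame(
          subject = keys$subject[i], season = keys$season[i],
          qc$removals, row.names = NULL)
      fit <- tryCatch(melatonin_acrophase(prof), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = keys$subject[i], season = keys$season[i],
        n_valid = sum(prof$valid),
        acrophase_h = if (is.null(fit)) NA_real_ else fit$acrophase_h,
        amplitude = if (is.null(fit)) NA_real_ else fit$amplitude,
        mesor = if (is.null(fit)) NA_real_ else fit$mesor,
        p_zero_amp = if (is.null(fit)) NA_real_ else fit$p_zero_amp)
    }
    tab <- do.call(rbind, rows)
    write_tsv(tab, file.path(out_dir, "melatonin_acrophase.tsv"))
    audit_tab <- if (length(audit)) do.call(rbind, audit) else
      data.frame(subject = character(), season = character(),
                 time_h = numeric(), concentration = numeric(),
                 reason = character())
    write_tsv(audit_tab, file.path(out_dir, "melatonin_qc.tsv"))
    tab
  })

  ## --- associate ----------------------------------------------------
  assoc <- stage("associate", {
    cohort <- read_tsv(file.path(out_dir, "cohort.tsv"))
    cohort$tg_hdl <- cohort$tg / cohort$hdl
    blue <- metrics_tab[metrics_tab$channel == "blue_irradiance", ]
    cohort <- merge(cohort, blue[setdiff(names(blue), "channel")],
                    by = c("subject", "season"), sort = TRUE)
    cohort <- merge(cohort,
                    setNames(mel_acro[c("subject", "season", "acrophase_h")],
                             c("subject", "season", "melatonin_acrophase_h")),
                    by = c("subject", "season"), all.x = TRUE, sort = TRUE)
    tabs <- associate_cohort(cohort, fdr = config$stats$fdr,
                             family = config$stats$family)
    write_tsv(tabs$correlations, file.path(out_dir, "table1_correlations.tsv"))
    write_tsv(tabs$photoperiod_adjusted, file.path(out_dir, "table2_adjusted.tsv"))
    write_tsv(tabs$demographics, file.path(out_dir, "table4_demographics.tsv"))
    write_tsv(tabs$fully_adjusted, file.path(out_dir, "fig1_matrix.tsv"))
    cohort
  })

  ## --- rhythm -------------------------------------------------------
  stage("rhythm", {
    files <- file.path(out_dir, sprintf("light_%s_%s.csv",
                                        assoc$subject, assoc$season))
    series <- lapply(files, function(f) read_epoch_csv(f)$blue)
    expo <- epoch_exposure_matrix(series, epoch_min = config$rhythm$epoch_min)
    summ <- list()
    for (lp in c("hdl", "tg")) {
      cr <- correlation_rhythm(expo, assoc[[lp]], fdr = config$stats$fdr,
                               fisher_z = config$rhythm$fisher_z)
      write_tsv(data.frame(epoch_center_h = cr$epoch_centers_h,
                           r = cr$r_values, p = cr$p_values,
                           flagged = cr$significant_mask),
                file.path(out_dir, sprintf("rhythm_%s.tsv", lp)))
      summ[[lp]] <- data.frame(
        lipid = lp, mesor = cr$r_cosinor$mesor,
        amplitude = cr$r_cosinor$amplitude,
        acrophase_h = cr$r_cosinor$acrophase_h,
        f = cr$r_cosinor$f_zero_amp, p = cr$r_cosinor$p_zero_amp)
    }
    write_tsv(do.call(rbind, summ), file.path(out_dir, "rhythm_summary.tsv"))
  })

  ## --- manifest -----------------------------------------------------
  cfg_yaml <- yaml::as.yaml(config)
  tmp <- tempfile(); writeLines(cfg_yaml, tmp)
  cfg_hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    config_hash = cfg_hash,
    seed = config$seed,
    package_version = as.character(packageVersion("circalipid")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    files = as.list(setNames(unname(tools::md5sum(file.path(out_dir, outputs))),
                             outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
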