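test_that("light series generation is bit-identical under a fixed seed", {
  prof <- season_profiles()["SE", ]
  a <- generate_light_series(prof, seed = 99)
  b <- generate_light_series(prof, seed = 99)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- generate_light_series(prof, seed = 100)
  expect_false(identical(a$blue$values, c$blue$values))
})

test_that("degenerate profile draws collapse to a constant series", {
  prof <- season_profiles()["WS", ]
  rec <- generate_light_series(prof, seed = 1, noise_sigma = 0,
                               params = data.frame(mesor = 3, na = 0,
                                                   amplitude = 0, lan = 0,
                                                   lan_onset_h = 2))
  expect_true(all(abs(rec$blue$values - 3) < 1e-12))
})

test_that("a noiseless waveform reproduces its planted endpoints", {
  prof <- season_profiles()["SE", ]
  # nocturnal trough well separated from the bright window: the planted
  # cosinor triple and the L5 level/onset are then exact by construction
  pars <- data.frame(mesor = 11, na = 1.4, amplitude = 15.4,
                     acrophase_h = 13, lan = 0.08, lan_onset_h = 1.3)
  rec <- generate_light_series(prof, seed = 5, noise_sigma = 0,
                               params = pars)
  fit <- fit_cosinor(rec$blue)
  expect_equal(fit$mesor, 11, tolerance = 1e-6)
  expect_equal(fit$amplitude, 15.4, tolerance = 2e-3)
  expect_lt(abs(fit$acrophase_h - 13) * 60, 1)
  np <- nonparametric_metrics(rec$blue, fit)
  expect_equal(np$l5, 0.08, tolerance = 1e-3)
  d5 <- abs(np$l5_onset_h - 1.3)
  expect_lt(min(d5, 24 - d5), 0.25)
  # white channel is an exact fixed multiple of blue
  expect_equal(rec$white$values, 7 * rec$blue$values, tolerance = 1e-12)
})

test_that("random draws keep fitted endpoints near the latent ones", {
  prof <- season_profiles()["SE", ]
  errs <- vapply(1:30, function(i) {
    rec <- generate_light_series(prof, seed = 400 + i, noise_sigma = 0)
    fit <- fit_cosinor(rec$blue)
    np <- nonparametric_metrics(rec$blue, fit)
    c(mesor = abs(fit$mesor / rec$params$mesor - 1),
      l5 = abs(np$l5 / rec$params$lan - 1))
  }, numeric(2))
  expect_lt(max(errs["mesor", ]), 1e-6)
  # the L5 target is approximate when the drawn trough abuts the bright
  # window; typically it is tight
  expect_lt(median(errs["l5", ]), 0.02)
})

test_that("seasonal cohorts calibrate to their configured targets", {
  prof <- season_profiles()["WS", ]
  fits <- lapply(1:80, function(i) {
    rec <- generate_light_series(prof, seed = 300 + i)
    f <- fit_cosinor(rec$blue)
    c(mesor = f$mesor, na = normalized_amplitude(f))
  })
  fits <- do.call(rbind, fits)
  se_m <- prof$mesor_sd / sqrt(nrow(fits))
  se_na <- prof$na_sd / sqrt(nrow(fits))
  expect_lt(abs(mean(fits[, "mesor"]) - prof$mesor_mean), 3 * se_m)
  expect_lt(abs(mean(fits[, "na"]) - prof$na_mean), 3 * se_na)
})

test_that("cohorts are reproducible and shaped as subject x season", {
  a <- generate_cohort(8, seed = 21)
  b <- generate_cohort(8, seed = 21)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_equal(nrow(a), 24)
  expect_equal(as.integer(table(a$subject)), rep(3L, 8))
  expect_true(all(a$photoperiod_h[a$season == "WS"] == 1))
  expect_true(all(a$photoperiod_h[a$season == "SS"] == 23))
  expect_true(all(a$tg > 0 & a$hdl > 0))
  expect_equal(a$tg_hdl, a$tg / a$hdl)
})

test_that("analytic and series methods agree on the planted endpoints", {
  coh_a <- generate_cohort(8, seed = 33, method = "analytic")
  coh_s <- generate_cohort(8, seed = 33, method = "series")
  for (col in c("mesor", "na", "acrophase_h", "l5")) {
    expect_gt(cor(coh_a[[col]], coh_s[[col]]), 0.95)
  }
})

test_that("a two-subject cohort is valid but refuses adjusted models", {
  coh <- generate_cohort(2, seed = 3)
  expect_equal(nrow(coh), 6)
  expect_error(fully_adjusted_model(coh, "tc", "l5"), "insufficient df")
})

test_that("unknown predictors and oversized effects are rejected", {
  bad <- data.frame(outcome = "tg", predictor = "nonesuch", beta = 0.2)
  expect_error(generate_cohort(5, effects = bad, seed = 1), "unknown predictor")
  big <- data.frame(outcome = c("tg", "tg"), predictor = c("na", "l5"),
                    beta = c(0.9, 0.8))
  expect_error(generate_cohort(5, effects = big, seed = 1), "R-squared")
  expect_error(generate_cohort(1, seed = 1), "at least 2")
})

test_that("null cohorts produce flag rates at or below the FDR level", {
  set.seed(5)
  flagged <- vapply(1:60, function(i) {
    coh <- generate_cohort(27, effects = effect_spec(null = TRUE),
                           seed = 4000 + i)
    t1 <- simple_correlations(coh,
                              predictors = c("na", "l5", "acrophase_h",
                                             "m10", "ra"),
                              outcomes = c("tc", "hdl", "tg"))
    any(t1$p_rank_significant)
  }, TRUE)
  mc_se <- sqrt(0.1 * 0.9 / length(flagged))
  expect_lte(mean(flagged), 0.1 + 3 * mc_se)
})

test_that("the planted cosinor geometry is solvable across the target range", {
  # window width/height solver: closed-form round trip
  for (na in c(0.3, 0.8, 1.2, 1.6, 1.8)) {
    g <- circalipid:::solve_window(10, na * 10, 0.2)
    w <- 2 * pi / 24
    expect_equal(0.2 + g$height * g$width_h / 24, 10, tolerance = 1e-6)
    expect_equal((2 * g$height / pi) * sin(pi * g$width_h / 24), na * 10,
                 tolerance = na * 10 * 0.02)
  }
})
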