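test_that("noiseless cosine is recovered exactly", {
  t <- seq(0, 24 * 7 - 1 / 60, by = 1 / 60)
  y <- 10 + 5 * cos(2 * pi * (t - 14) / 24)
  fit <- fit_cosinor(epoch_series(y))
  expect_lt(abs(fit$mesor - 10), 1e-9)
  expect_lt(abs(fit$amplitude - 5), 1e-9)
  expect_lt(abs(fit$acrophase_h - 14) * 3600, 1)
  expect_lt(fit$rss, 1e-12)
  expect_lt(fit$p_zero_amp, 1e-12)
})

test_that("constant series has zero amplitude and undefined acrophase", {
  fit <- fit_cosinor(epoch_series(rep(7.5, 1440)))
  expect_equal(fit$mesor, 7.5)
  expect_lt(fit$amplitude, 1e-9)
  expect_true(fit$undefined_acrophase)
  expect_true(is.na(fit$acrophase_h))
  expect_equal(fit$p_zero_amp, 1)
})

test_that("cosinor matches the exhaustive acrophase-grid oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    t <- sort(runif(300, 0, 48))
    y <- 8 + 3 * cos(2 * pi * (t - runif(1, 0, 24)) / 24) + rnorm(300, 0, 1.5)
    fit <- cosinor_lm(t, y)
    orc <- oracle_cosinor_grid(t, y, step_s = 1)
    expect_lt(abs(fit$mesor - orc$mesor), 1e-3)
    expect_lt(abs(fit$amplitude - orc$amplitude), 1e-3)
    d <- abs(fit$acrophase_h - orc$acrophase_h)
    expect_lt(min(d, 24 - d) * 3600, 2) # within grid resolution
    expect_lte(fit$rss, orc$sse + 1e-8)
  }
})

test_that("cosinor is shift- and scale-equivariant", {
  for (seed in 1:10) {
    s <- random_light_series(seed, days = 3)
    f0 <- fit_cosinor(s)
    delta <- (seed * 3.7) %% 24
    shifted <- epoch_series(s$values, start_h = (s$start_h + delta) %% 24)
    f1 <- fit_cosinor(shifted)
    expect_equal(f1$mesor, f0$mesor, tolerance = 1e-10)
    expect_equal(f1$amplitude, f0$amplitude, tolerance = 1e-10)
    d <- abs(f1$acrophase_h - (f0$acrophase_h + delta) %% 24)
    expect_lt(min(d, 24 - d), 1e-6)
    k <- 1 + seed / 3
    f2 <- fit_cosinor(epoch_series(k * s$values, start_h = s$start_h))
    expect_equal(f2$mesor, k * f0$mesor, tolerance = 1e-10)
    expect_equal(f2$amplitude, k * f0$amplitude, tolerance = 1e-10)
    expect_equal(normalized_amplitude(f2), normalized_amplitude(f0),
                 tolerance = 1e-10)
  }
})

test_that("parameter estimates are unbiased on self-generated noisy data", {
  t <- seq(0, 24 * 7 - 1 / 60, by = 1 / 60)
  mu <- 10 + 4 * cos(2 * pi * (t - 15) / 24)
  set.seed(42)
  est <- replicate(30, {
    f <- cosinor_lm(t, mu + rnorm(length(t), 0, 3))
    c(f$mesor, f$amplitude, f$acrophase_h)
  })
  mc_se <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_lt(abs(mean(est[1, ]) - 10), 4 * mc_se[1] + 1e-4)
  expect_lt(abs(mean(est[2, ]) - 4), 4 * mc_se[2] + 1e-4)
  expect_lt(abs(mean(est[3, ]) - 15), 4 * mc_se[3] + 1e-3)
})

test_that("degenerate inputs are rejected", {
  expect_error(cosinor_lm(c(1, 2, 3), c(1, 2, 3)), "half a period")
  expect_error(cosinor_lm(rep(1, 10), rnorm(10)), "distinct")
  expect_error(fit_cosinor(epoch_series(rep(NA_real_, 1440))), "3 distinct")
  expect_error(epoch_series(rep(1, 100)), "1440")
  expect_error(epoch_series(c(-1, rep(1, 1439))), "non-negative")
})

test_that("normalized amplitude follows its definition and fails for MESOR <= 0", {
  f <- list(mesor = 10, amplitude = 5, undefined_acrophase = FALSE)
  class(f) <- "cosinor"
  expect_equal(normalized_amplitude(f), 0.5)
  f$amplitude <- 0
  expect_equal(normalized_amplitude(f), 0)
  f$mesor <- 0
  expect_error(normalized_amplitude(f), "undefined")
})

test_that("circular mean handles wraparound, ties and degeneracy", {
  m <- circular_mean_clock(c(23.5, 0.5))$mean_h
  expect_lt(min(m, 24 - m), 1e-9) # midnight, up to the circular identity
  expect_equal(circular_mean_clock(c(6, 6, 6))$mean_h, 6)
  sym <- circular_mean_clock(c(0, 8, 16))
  expect_true(is.na(sym$mean_h))
  expect_lt(sym$resultant, 1e-9)
  expect_error(circular_mean_clock(numeric()), "empty")
})

test_that("clock unwrapping maps times into a contiguous window", {
  x <- c(23.5, 0.2, 1.1, 22.8)
  u <- unwrap_clock(x)
  expect_lt(diff(range(u)), 3)
  expect_equal(sort(u %% 24), sort(x))
  # values already contiguous are preserved up to the circular identity
  expect_equal(unwrap_clock(c(10, 11, 12)), c(10, 11, 12))
})
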