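test_that("epoch matrix reproduces constants and square-wave edges", {
  const <- epoch_series(rep(3, 2880))
  m <- epoch_exposure_matrix(list(const))
  expect_equal(dim(m), c(1, 48))
  expect_true(all(m == 3))
  expect_equal(attr(m, "centers_h")[1], 0.25)

  # plateau 100 on [08:15, 20:00): the 08:00-08:30 epoch straddles the
  # edge (15 dark + 15 lit minutes -> 50), full epochs read 100 or 0
  day <- numeric(1440)
  day[(8 * 60 + 15 + 1):(20 * 60)] <- 100
  m2 <- epoch_exposure_matrix(list(epoch_series(rep(day, 2))))
  expect_equal(m2[1, 17], 50) # 08:00-08:30
  expect_equal(m2[1, 18], 100)
  expect_equal(m2[1, 40], 100) # 19:30-20:00
  expect_equal(m2[1, 41], 0)
  expect_equal(m2[1, 1], 0)

  expect_error(epoch_exposure_matrix(list(const), epoch_min = 7), "divide")
})

test_that("epoch-wise correlations find planted structure and stay null-safe", {
  set.seed(30)
  mat <- matrix(rlnorm(500 * 48), 500, 48)
  lipid <- mat[, 17]
  ec <- epochwise_correlation(mat, lipid)
  expect_equal(ec$r[17], 1)
  expect_lt(max(abs(ec$r[-17])), 0.2)

  # lipid built from the 08:00-10:00 morning mean + noise
  lipid2 <- rowMeans(mat[, 17:20]) + rnorm(500, 0, 0.05)
  ec2 <- epochwise_correlation(mat, lipid2)
  expect_true(which.max(ec2$r) %in% 17:20)

  # independent lipid: false flags stay at or below the FDR level
  ec3 <- epochwise_correlation(mat, rnorm(500))
  expect_lt(max(abs(ec3$r)), 0.2)
  expect_lte(mean(significant_epoch_mask(ec3$p)), 0.1)

  # zero-variance epochs are undefined, excluded from the family
  mat[, 5] <- 1
  ec4 <- epochwise_correlation(mat, lipid)
  expect_true(is.na(ec4$r[5]))
  expect_false(significant_epoch_mask(ec4$p)[5])

  expect_error(epochwise_correlation(mat[1:3, ], lipid[1:3]), "4 rows")
})

test_that("the r-curve cosinor recovers exact and degenerate inputs", {
  centers <- (1:48 - 0.5) / 2
  r <- 0.2 * cos(2 * pi * (centers - (8 + 55 / 60)) / 24)
  fit <- fit_r_rhythm(r, centers)
  expect_lt(abs(fit$acrophase_h - (8 + 55 / 60)) * 60, 0.1)
  expect_lt(fit$rss, 1e-20)

  flat <- fit_r_rhythm(rep(0.1, 48), centers)
  expect_lt(flat$amplitude, 1e-9)
  expect_equal(flat$f_zero_amp, 0)

  expect_error(fit_r_rhythm(c(0.1, 0.2, NA, NA), centers[1:4]), "4 defined")
})

test_that("the epoch mask flags exactly the step-up significant epochs", {
  p <- rep(0.5, 48)
  expect_equal(sum(significant_epoch_mask(p)), 0)
  p[13] <- 1e-6
  m <- significant_epoch_mask(p)
  expect_identical(which(m), 13L)
})

test_that("planted antiphase structure is recovered with its separation", {
  rc <- generate_rhythm_cohort(150, seed = 44)
  f_h <- fit_r_rhythm(epochwise_correlation(rc$exposure, rc$lipids$hdl)$r,
                      rc$centers_h)
  f_t <- fit_r_rhythm(epochwise_correlation(rc$exposure, rc$lipids$tg)$r,
                      rc$centers_h)
  d_h <- abs(f_h$acrophase_h - rc$truth[["hdl"]])
  d_t <- abs(f_t$acrophase_h - rc$truth[["tg"]])
  expect_lt(min(d_h, 24 - d_h), 1)
  expect_lt(min(d_t, 24 - d_t), 1)
  sep <- abs(f_h$acrophase_h - f_t$acrophase_h) %% 24
  sep <- min(sep, 24 - sep)
  # the day/night antiphase pattern: peaks on opposite sides of the
  # cycle (the planted circular separation is 9.28 h)
  expect_gt(sep, 8)
  expect_lt(sep, 11)
})

test_that("minute-resolution and epoch-resolution generators agree", {
  rc_m <- generate_rhythm_cohort(60, resolution = "minute", seed = 45)
  cr <- correlation_rhythm(rc_m$exposure, rc_m$lipids$hdl)
  d <- abs(cr$r_cosinor$acrophase_h - rc_m$truth[["hdl"]])
  expect_lt(min(d, 24 - d), 1.5)
  expect_equal(dim(rc_m$exposure), c(60, 48))
  expect_length(rc_m$recordings, 60)
})

test_that("the workflow is equivariant to shifting the light clock", {
  rc <- generate_rhythm_cohort(60, resolution = "minute", seed = 46)
  base <- correlation_rhythm(rc$exposure, rc$lipids$hdl)$r_cosinor
  delta <- 6
  shifted <- lapply(rc$recordings, function(s)
    epoch_series(s$values, start_h = (s$start_h + delta) %% 24))
  shift_fit <- correlation_rhythm(shifted, rc$lipids$hdl)$r_cosinor
  d <- abs(shift_fit$acrophase_h - (base$acrophase_h + delta) %% 24)
  expect_lt(min(d, 24 - d), 0.3)
})

test_that("the zero-amplitude test is calibrated under the global null", {
  rej <- vapply(1:200, function(i) {
    rc <- generate_rhythm_cohort(40, null = TRUE, seed = 8000 + i)
    fit_r_rhythm(epochwise_correlation(rc$exposure, rc$lipids$hdl)$r,
                 rc$centers_h)$p_zero_amp < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.05 - 3 * sqrt(0.05 * 0.95 / 200))
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})
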