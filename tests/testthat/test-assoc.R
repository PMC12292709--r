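test_that("BH step-up flags match hand-applied rule", {
  expect_identical(bh_adjust(c(0.001, 0.01, 0.02, 0.04, 0.2), fdr = 0.1),
                   c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(bh_adjust(rep(0.9, 6)), rep(FALSE, 6))
  expect_identical(bh_adjust(0.05, fdr = 0.1), TRUE)
  # NA p-values are excluded from the family
  expect_identical(bh_adjust(c(0.001, NA, 0.2), fdr = 0.1),
                   c(TRUE, FALSE, FALSE))
  expect_error(bh_adjust(numeric()), "empty")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH flags agree with p.adjust thresholding on random inputs", {
  set.seed(2)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- runif(1, 0.02, 0.3)
    expect_identical(bh_adjust(p, q), p.adjust(p, "BH") <= q)
  }
})

test_that("pooled correlations reproduce closed-form cases", {
  df <- data.frame(x = c(1, 2, 3, 4, 5, 6), y = c(2, 1, 4, 3, 6, 5))
  res <- simple_correlations(df, predictors = "x", outcomes = "y")
  r_hand <- sum((df$x - 3.5) * (df$y - 3.5)) /
    sqrt(sum((df$x - 3.5)^2) * sum((df$y - 3.5)^2))
  expect_equal(res$estimate, r_hand, tolerance = 1e-12)
  expect_equal(res$variance_explained, r_hand^2, tolerance = 1e-12)

  ident <- data.frame(x = rnorm(20))
  ident$y <- ident$x
  expect_equal(simple_correlations(ident, "x", "y")$estimate, 1)

  set.seed(8)
  big <- data.frame(x = rnorm(10000), y = rnorm(10000))
  expect_lt(abs(simple_correlations(big, "x", "y")$estimate), 0.05)

  expect_error(simple_correlations(data.frame(x = rep(1, 10), y = rnorm(10)),
                                   "x", "y"), "zero-variance")
})

test_that("standardized beta equals r when no covariates are included", {
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(40); y <- 0.4 * x + rnorm(40)
    fit <- circalipid:::std_lm(y, x, list())
    expect_equal(fit$beta, cor(x, y), tolerance = 1e-12)
  }
})

test_that("photoperiod-adjusted model matches the normal-equation oracle", {
  coh <- toy_cohort(40, seed = 4)
  res <- photoperiod_adjusted_model(coh, "tg", "na")
  orc <- oracle_std_fit(coh$tg, cbind(coh$na, coh$photoperiod_h))
  expect_equal(res$estimate, orc$beta, tolerance = 1e-10)
  expect_equal(res$variance_explained, orc$r2, tolerance = 1e-10)

  # outcome equal to the predictor, photoperiod orthogonal by construction
  coh$yx <- coh$na
  res2 <- photoperiod_adjusted_model(coh, "yx", "na")
  expect_equal(res2$estimate, 1, tolerance = 1e-8)
  expect_equal(res2$variance_explained, 1, tolerance = 1e-8)

  expect_error(photoperiod_adjusted_model(coh[1:4, ], "tg", "na"),
               "insufficient df")
})

test_that("fully adjusted beta and partial eta-squared match the RSS oracle", {
  set.seed(6)
  for (i in 1:20) {
    coh <- toy_cohort(50, seed = 600 + i)
    res <- fully_adjusted_model(coh, "tc", "l5")
    X <- cbind(coh$l5, coh$photoperiod_h, coh$age,
               as.numeric(coh$sex == "male"),
               as.numeric(coh$indigeneity == "NN"))
    orc <- oracle_std_fit(coh$tc, X)
    expect_lt(abs(res$estimate - orc$beta), 1e-10)
    expect_lt(abs(res$variance_explained - orc$partial_eta2), 1e-10)
  }
})

test_that("fully adjusted model cross-checks against car's Type III ANOVA", {
  coh <- toy_cohort(60, seed = 11)
  res <- fully_adjusted_model(coh, "tg", "na")
  d <- data.frame(y = scale(coh$tg)[, 1], x = scale(coh$na)[, 1],
                  ph = scale(coh$photoperiod_h)[, 1],
                  age = scale(coh$age)[, 1],
                  male = scale(as.numeric(coh$sex == "male"))[, 1],
                  nn = scale(as.numeric(coh$indigeneity == "NN"))[, 1])
  fit <- lm(y ~ x + ph + age + male + nn, data = d)
  a3 <- car::Anova(fit, type = 3)
  ss_x <- a3["x", "Sum Sq"]; ss_res <- a3["Residuals", "Sum Sq"]
  expect_equal(res$variance_explained, ss_x / (ss_x + ss_res),
               tolerance = 1e-10)
  expect_equal(res$p, a3["x", "Pr(>F)"], tolerance = 1e-10)
})

test_that("perfect-fit designs give partial eta-squared of one", {
  coh <- toy_cohort(30, seed = 14)
  coh$y <- coh$na
  res <- fully_adjusted_model(coh, "y", "na")
  expect_equal(res$variance_explained, 1)
})

test_that("type-I error of the adjusted model is calibrated under the null", {
  set.seed(10)
  hits <- vapply(1:600, function(i) {
    coh <- generate_cohort(10, effects = effect_spec(null = TRUE),
                           seed = 7000 + i)
    photoperiod_adjusted_model(coh, "tg", "na")$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})

test_that("VIF matches closed forms and the auxiliary-regression oracle", {
  set.seed(12)
  n <- 4000
  a <- rnorm(n)
  b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(n)
  v <- vif(cbind(a = a, b = b))
  expect_equal(unname(v["b"]), 1 / (1 - cor(a, b)^2), tolerance = 1e-10)
  expect_equal(unname(v["b"]), 5.263, tolerance = 0.7) # 1/(1-0.81)

  d3 <- data.frame(x1 = rnorm(50), x2 = rnorm(50), x3 = rnorm(50))
  d3$x3 <- d3$x3 + 0.5 * d3$x1
  v3 <- vif(d3)
  d3$y <- rnorm(50)
  expect_equal(unname(v3), unname(car::vif(lm(y ~ x1 + x2 + x3, d3))),
               tolerance = 1e-8)

  Xc <- cbind(a = a[1:20], b = 2 * a[1:20])
  expect_true(is.infinite(vif(Xc)["b"]))
  expect_error(vif(cbind(a = rep(1, 10), b = rnorm(10))), "constant")
})

test_that("orthogonal columns have unit VIF", {
  t <- 1:120
  # sinusoidal harmonics: zero-mean, mutually orthogonal by construction
  X <- cbind(sin(2 * pi * t / 120), cos(2 * pi * t / 120),
             sin(4 * pi * t / 120))
  v <- vif(X)
  expect_true(all(abs(v - 1) < 1e-8))
})

test_that("seasonal comparison routes by normality and detects separation", {
  set.seed(13)
  # clearly normal groups -> parametric route
  coh_n <- data.frame(season = rep(c("WS", "SE", "SS"), each = 40),
                      v = rnorm(120, rep(c(0, 0, 0), each = 40)))
  cs_n <- compare_seasons(coh_n, "v")
  expect_equal(cs_n$route, "parametric")
  expect_equal(cs_n$omnibus$method, "anova")
  # heavy-tailed log-normal groups -> rank route
  coh_l <- data.frame(season = rep(c("WS", "SE", "SS"), each = 40),
                      v = rlnorm(120, 0, 1.2))
  cs_l <- compare_seasons(coh_l, "v")
  expect_equal(cs_l$route, "rank")
  expect_equal(cs_l$omnibus$method, "kruskal-wallis")
  # two seasons shifted by five SDs: overwhelming significance
  coh_s <- data.frame(season = rep(c("WS", "SE"), each = 27),
                      v = c(rnorm(27), rnorm(27, 5)))
  expect_lt(compare_seasons(coh_s, "v")$omnibus$p, 1e-3)
  expect_error(compare_seasons(data.frame(season = "WS", v = 1), "v"),
               "2 seasons|3 values")
})

test_that("Kruskal-Wallis rejection rate is nominal under identical groups", {
  set.seed(15)
  rej <- vapply(1:400, function(i) {
    coh <- data.frame(season = rep(c("WS", "SE", "SS"), each = 15),
                      v = rlnorm(45))
    compare_seasons(coh, "v")$omnibus$p < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("sign conventions follow the planted direction of effects", {
  coh <- generate_cohort(300, seed = 17)
  # earlier blue-light acrophase planted to raise HDL-C: negative beta
  expect_lt(fully_adjusted_model(coh, "hdl", "acrophase_h")$estimate, 0)
  # melatonin models run on the complete-case subset
  res <- simple_correlations(coh, "melatonin_acrophase_h", "tg")
  expect_lt(res$n, nrow(coh))
  expect_gt(res$estimate, 0)
})

test_that("the association battery produces one row per pair and table", {
  coh <- generate_cohort(27, seed = 19)
  tabs <- associate_cohort(coh)
  preds <- 10 # 9 light metrics + melatonin acrophase
  expect_equal(nrow(tabs$correlations), (preds + 1) * 5)
  expect_equal(nrow(tabs$photoperiod_adjusted), preds * 5)
  expect_equal(nrow(tabs$fully_adjusted), preds * 5)
  expect_equal(nrow(tabs$demographics), 4 * 5)
  expect_true(all(tabs$fully_adjusted$variance_explained >= 0 &
                  tabs$fully_adjusted$variance_explained <= 1))
  expect_true(all(abs(tabs$correlations$estimate) <= 1))
})
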