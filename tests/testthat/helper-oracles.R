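# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, grids and explicit linear algebra.

# literal scan over all 1440 cyclic window starts on a 1440-long day
oracle_window <- function(day, width, which = "max") {
  xx <- c(day, day)
  means <- vapply(1:1440, function(s) mean(xx[s:(s + width - 1)]), 0)
  idx <- if (which == "max") which.max(means) else which.min(means)
  list(level = means[idx], onset_h = (idx - 1) / 60)
}

# exhaustive acrophase grid search: for each candidate acrophase the
# remaining (mesor, amplitude) fit is a one-regressor least squares with
# closed form; returns the grid point minimizing the SSE
oracle_cosinor_grid <- function(time_h, y, step_s = 1, period_h = 24) {
  w <- 2 * pi / period_h
  C <- cos(w * time_h); S <- sin(w * time_h)
  phis <- seq(0, period_h, by = step_s / 3600); phis <- phis[phis < period_h]
  cw <- cos(w * phis); sw <- sin(w * phis)
  n <- length(y)
  # sufficient statistics for c_phi = C*cw + S*sw
  sum_c <- cw * sum(C) + sw * sum(S)
  sum_c2 <- cw^2 * sum(C^2) + 2 * cw * sw * sum(C * S) + sw^2 * sum(S^2)
  sum_yc <- cw * sum(y * C) + sw * sum(y * S)
  sy <- sum(y)
  # regression of y on [1, c_phi]
  den <- n * sum_c2 - sum_c^2
  a <- (n * sum_yc - sum_c * sy) / den
  m <- (sy - a * sum_c) / n
  sse <- sum(y^2) - (m * sy + a * sum_yc)
  best <- which.min(sse)
  list(mesor = m[best], amplitude = abs(a[best]),
       acrophase_h = if (a[best] >= 0) phis[best]
                     else (phis[best] + period_h / 2) %% period_h,
       sse = sse[best])
}

# explicit normal-equation fit of z-scored outcome on z-scored columns;
# returns the first column's coefficient plus the two-model RSS ratio
oracle_std_fit <- function(y, X) {
  z <- function(v) (v - mean(v)) / sd(v)
  yz <- z(y)
  Xz <- apply(X, 2, z)
  A <- cbind(1, Xz)
  b <- solve(t(A) %*% A, t(A) %*% yz)
  rss_full <- sum((yz - A %*% b)^2)
  Ar <- A[, -2, drop = FALSE]
  br <- solve(t(Ar) %*% Ar, t(Ar) %*% yz)
  rss_red <- sum((yz - Ar %*% br)^2)
  list(beta = b[2],
       partial_eta2 = (rss_red - rss_full) / rss_red,
       r2 = 1 - rss_full / sum(yz^2))
}

# random 7-day light-like series with gentle diurnal structure
random_light_series <- function(seed, days = 7) {
  set.seed(seed)
  n <- days * 1440
  t <- (seq_len(n) - 1) / 60
  base <- 2 + runif(1, 0, 5) * (1 + cos(2 * pi * (t - runif(1, 0, 24)) / 24))
  epoch_series(pmax(base * exp(rnorm(n, 0, 0.4)), 0))
}

# small cohort-shaped data frame with independent columns, for model
# plumbing tests that do not need the full generator
toy_cohort <- function(n = 60, seed = 1) {
  set.seed(seed)
  data.frame(
    subject = sprintf("S%02d", seq_len(n)),
    season = rep(c("WS", "SE", "SS"), length.out = n),
    photoperiod_h = rep(c(1, 12, 23), length.out = n),
    age = sample(18:59, n, TRUE),
    sex = sample(c("female", "male"), n, TRUE),
    indigeneity = sample(c("N", "NN"), n, TRUE),
    na = rnorm(n, 1.3, 0.2),
    l5 = rlnorm(n, -2, 1),
    acrophase_h = (rnorm(n, 13.5, 1.2)) %% 24,
    tc = rnorm(n, 5, 1),
    hdl = rnorm(n, 1.4, 0.35),
    tg = rlnorm(n, 0.2, 0.4)
  )
}
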