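# Association battery: pooled correlations, photoperiod-adjusted and fully
# adjusted linear models, BH-FDR flags, VIF, seasonal comparisons.
# All subject-seasons are pooled as independent rows, mirroring the
# "overall data" analyses of the emulated design; no mixed-effects subject
# term is fitted (a known simplification, documented in the vignette).

default_light_predictors <- function() {
  c("mesor", "amplitude", "acrophase_h", "m10", "m10_onset_h",
    "l5", "l5_onset_h", "ra", "na")
}

default_outcomes <- function() c("tc", "ldl", "hdl", "tg", "tg_hdl")

# analysis-ready predictor column: circular clock variables unwrapped
assoc_column <- function(cohort, name) {
  if (!name %in% names(cohort)) stop("unknown column: ", name)
  v <- cohort[[name]]
  if (is_circular_name(name)) v <- unwrap_clock(v)
  v
}

#' Benjamini-Hochberg step-up significance flags
#'
#' Classic step-up rule controlling the false discovery rate at level
#' `fdr`: sort the m p-values ascending, find the largest rank `i` with
#' `p(i) <= (i/m) * fdr`, and flag all hypotheses of rank `<= i`. `NA`
#' p-values are excluded from the family and returned unflagged.
#'
#' @param pvalues numeric vector of p-values in `(0, 1]`.
#' @param fdr the FDR level `q` (default 0.1).
#' @return logical vector of the same length: `TRUE` = significant after
#'   correction.
#' @examples
#' bh_adjust(c(0.001, 0.01, 0.02, 0.04, 0.2), fdr = 0.1)
#' @export
bh_adjust <- function(pvalues, fdr = 0.1) {
  if (length(pvalues) == 0L) stop("empty p-value vector")
  if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1)
    stop("fdr must lie in (0, 1)")
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  # p = 0 arises from numerically perfect fits and is trivially flagged
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  flag <- logical(length(pvalues))
  if (m > 0L) {
    o <- order(p)
    below <- p[o] <= (seq_len(m) / m) * fdr
    k <- if (any(below)) max(which(below)) else 0L
    f <- logical(m)
    if (k > 0L) f[o[seq_len(k)]] <- TRUE
    flag[ok] <- f
  }
  flag
}

#' Pooled correlations between predictors and outcomes
#'
#' Pearson correlations (with two-sided p-values) of each predictor with
#' each outcome over the pooled subject-season rows, followed by
#' Benjamini-Hochberg flagging across the requested family. Clock-valued
#' predictors are linearized with [unwrap_clock()] first. Rows with
#' missing values in a pair are dropped pairwise (melatonin models thus
#' run on the complete-case subset).
#'
#' @param cohort a participant-season data frame ([generate_cohort()]).
#' @param predictors,outcomes column names; defaults cover the blue-light
#'   metrics plus photoperiod and melatonin acrophase against the five
#'   lipid endpoints.
#' @param fdr FDR level for the flags.
#' @param family `"all"` (one family across the whole table, default) or
#'   `"per_outcome"`.
#' @return data frame of association rows: `outcome`, `predictor`,
#'   `model = "simple"`, `estimate` (r), `variance_explained` (r^2), `p`,
#'   `p_rank_significant`, `n`.
#' @export
simple_correlations <- function(cohort,
                                predictors = c("photoperiod_h",
                                               default_light_predictors(),
                                               "melatonin_acrophase_h"),
                                outcomes = default_outcomes(),
                                fdr = 0.1,
                                family = c("all", "per_outcome")) {
  family <- match.arg(family)
  rows <- list()
  for (out in outcomes) {
    y_all <- cohort[[out]]
    for (pr in predictors) {
      x_all <- assoc_column(cohort, pr)
      ok <- is.finite(x_all) & is.finite(y_all)
      if (sum(ok) < 4L)
        stop(sprintf("fewer than 4 complete rows for %s ~ %s", out, pr))
      x <- x_all[ok]; y <- y_all[ok]
      if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop(sprintf("zero-variance variable in %s ~ %s", out, pr))
      ct <- stats::cor.test(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = out, predictor = pr, model = "simple",
        estimate = unname(ct$estimate),
        variance_explained = unname(ct$estimate)^2,
        p = ct$p.value, p_rank_significant = NA, n = sum(ok))
    }
  }
  res <- do.call(rbind, rows)
  res$p_rank_significant <- apply_family_flags(res, fdr, family)
  res
}

apply_family_flags <- function(res, fdr, family) {
  if (family == "all") return(bh_adjust(res$p, fdr))
  flags <- logical(nrow(res))
  for (out in unique(res$outcome)) {
    i <- res$outcome == out
    flags[i] <- bh_adjust(res$p[i], fdr)
  }
  flags
}

# shared z-scored least-squares fit returning the focal predictor's
# standardized beta, its p, model R2 and the Type III partial eta-squared
std_lm <- function(y, x, covars) {
  n <- length(y)
  # covariates constant on the analysis subset are non-identifiable and
  # are dropped; a constant focal predictor is still an error (zscore)
  covars <- covars[vapply(covars, function(v) stats::sd(v) > 0, TRUE)]
  X <- cbind(`(Intercept)` = 1, x = zscore(x))
  for (nm in names(covars)) X <- cbind(X, zscore(covars[[nm]]))
  colnames(X) <- c("(Intercept)", "x", names(covars))
  yz <- zscore(y)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  fit <- lm.fit(X, yz)
  res <- fit$residuals
  rss_full <- sum(res^2)
  # reduced model without the focal predictor (Type III / drop-one SS;
  # identical because every term enters once)
  Xr <- X[, colnames(X) != "x", drop = FALSE]
  rss_red <- sum(lm.fit(Xr, yz)$residuals^2)
  ss_pred <- rss_red - rss_full
  df_res <- n - ncol(X)
  beta <- fit$coefficients[["x"]]
  se <- if (rss_full <= 0) 0 else {
    XtXinv <- solve(crossprod(X))
    sqrt(rss_full / df_res * XtXinv[2, 2])
  }
  p <- if (se == 0) 0 else
    2 * stats::pt(abs(beta / se), df_res, lower.tail = FALSE)
  tss <- sum((yz - mean(yz))^2)
  list(beta = beta, p = p,
       r2 = 1 - rss_full / tss,
       partial_eta2 = if (ss_pred + rss_full <= 0) 0
                      else ss_pred / (ss_pred + rss_full),
       n = n)
}

#' Photoperiod-adjusted association model
#'
#' Ordinary least squares of the z-scored outcome on the z-scored
#' predictor plus z-scored photoperiod duration (1/12/23 h encoding).
#' Reports the predictor's standardized coefficient, the model R-squared
#' and the predictor's two-sided p-value.
#'
#' @inheritParams simple_correlations
#' @param outcome,predictor single column names.
#' @return one association row (`model = "photoperiod_adjusted"`,
#'   `variance_explained` = model R-squared).
#' @export
photoperiod_adjusted_model <- function(cohort, outcome, predictor) {
  x <- assoc_column(cohort, predictor)
  y <- cohort[[outcome]]
  ph <- cohort$photoperiod_h
  ok <- is.finite(x) & is.finite(y) & is.finite(ph)
  if (sum(ok) < 5L) stop("insufficient df: fewer than 5 complete rows")
  fit <- std_lm(y[ok], x[ok], list(photoperiod = ph[ok]))
  data.frame(outcome = outcome, predictor = predictor,
             model = "photoperiod_adjusted", estimate = fit$beta,
             variance_explained = fit$r2, p = fit$p,
             p_rank_significant = NA, n = fit$n)
}

#' Fully adjusted association model (ANCOVA)
#'
#' Least-squares fit of the z-scored outcome on the z-scored predictor
#' adjusting for photoperiod duration, age, sex (female = 0 / male = 1)
#' and indigeneity (native = 0 / non-native = 1). Reports the predictor's
#' standardized coefficient, its Type III partial eta-squared
#' (`SS_predictor / (SS_predictor + SS_residual)`, computed as the
#' drop-one residual-sum-of-squares difference, to which Type III reduces
#' when each term enters once) and its p-value. Design columns are
#' screened with [vif()]; any VIF above `vif_ceiling` attaches a warning
#' flag to the row.
#'
#' When the focal predictor is itself one of the covariates (a
#' demographic), that covariate is dropped from the adjustment set.
#'
#' @inheritParams photoperiod_adjusted_model
#' @param vif_ceiling multicollinearity warning threshold (default 5).
#' @return one association row (`model = "fully_adjusted"`,
#'   `variance_explained` = partial eta-squared) with a `vif_warning`
#'   column.
#' @export
fully_adjusted_model <- function(cohort, outcome, predictor,
                                 vif_ceiling = 5) {
  covars <- list(
    photoperiod = cohort$photoperiod_h,
    age = cohort$age,
    male = as.numeric(cohort$sex == "male"),
    nn = as.numeric(cohort$indigeneity == "NN"))
  x <- switch(predictor,
              age = cohort$age,
              male = as.numeric(cohort$sex == "male"),
              nn = as.numeric(cohort$indigeneity == "NN"),
              photoperiod = cohort$photoperiod_h,
              assoc_column(cohort, predictor))
  covars <- covars[setdiff(names(covars), predictor)]
  y <- cohort[[outcome]]
  ok <- is.finite(x) & is.finite(y)
  for (v in covars) ok <- ok & is.finite(v)
  if (sum(ok) < 8L) stop("insufficient df: fewer than 8 complete rows")
  covars <- lapply(covars, `[`, ok)
  fit <- std_lm(y[ok], x[ok], covars)
  design <- cbind(x = x[ok], as.data.frame(covars))
  vifs <- tryCatch(vif(design), error = function(e) rep(Inf, ncol(design)))
  out <- data.frame(outcome = outcome, predictor = predictor,
                    model = "fully_adjusted", estimate = fit$beta,
                    variance_explained = fit$partial_eta2, p = fit$p,
                    p_rank_significant = NA, n = fit$n)
  out$vif_warning <- any(!is.finite(vifs) | vifs > vif_ceiling)
  out
}

#' Demographic predictors of each outcome (fully adjusted model)
#'
#' One multiple regression per outcome on age, sex, indigeneity and
#' photoperiod simultaneously, reporting each covariate's standardized
#' coefficient — the demographic-effects table of the battery.
#'
#' @inheritParams simple_correlations
#' @return association rows (`model = "fully_adjusted"`), one per
#'   outcome-by-demographic pair.
#' @export
demographics_table <- function(cohort, outcomes = default_outcomes()) {
  rows <- list()
  for (out in outcomes) {
    for (pred in c("age", "male", "nn", "photoperiod")) {
      rows[[length(rows) + 1L]] <- na_row_on_error(
        fully_adjusted_model(cohort, out, pred), out, pred,
        "fully_adjusted", vif = TRUE)
    }
  }
  do.call(rbind, rows)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is the R-squared from regressing
#' design column `j` on all the others. Perfect collinearity yields `Inf`.
#'
#' @param design data frame or matrix of at least two non-constant
#'   numeric columns.
#' @return named numeric vector of VIFs.
#' @examples
#' vif(data.frame(a = rnorm(20), b = rnorm(20)))
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  if (ncol(X) < 2L) stop("VIF needs at least 2 columns")
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant design column")
  out <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    yj <- X[, j]
    Xj <- cbind(1, X[, -j, drop = FALSE])
    rss <- sum(lm.fit(Xj, yj)$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    r2 <- 1 - rss / tss
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  names(out) <- colnames(X)
  out
}

#' Seasonal comparison with normality-based test routing
#'
#' Compares a variable across seasons. Each seasonal group is screened
#' with the Shapiro-Wilk test and the Lilliefors (Kolmogorov-Smirnov)
#' test; if every group passes Shapiro-Wilk at `alpha` the route is
#' parametric (Student's t-tests pairwise, one-way ANOVA omnibus for 3+
#' groups), otherwise rank-based (Mann-Whitney pairwise, Kruskal-Wallis
#' omnibus). Both normality statistics are reported; Shapiro-Wilk is
#' decisive.
#'
#' @inheritParams simple_correlations
#' @param variable column name to compare.
#' @param alpha normality screening level (default 0.05).
#' @return list of class `season_comparison`: `variable`, `route`
#'   (`"parametric"` or `"rank"`), `normality` (per-season data frame),
#'   `omnibus` (statistic, p, method), `pairwise` (data frame of season
#'   pairs with statistic and p).
#' @export
compare_seasons <- function(cohort, variable, alpha = 0.05) {
  v <- cohort[[variable]]
  if (is.null(v)) stop("unknown column: ", variable)
  groups <- split(v[is.finite(v)], cohort$season[is.finite(v)])
  groups <- groups[vapply(groups, length, 0L) > 0]
  if (length(groups) < 2L) stop("fewer than 2 seasons present")
  if (any(vapply(groups, length, 0L) < 3L))
    stop("need at least 3 values per season")

  normality <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    sw <- stats::shapiro.test(x)
    lf <- tryCatch(nortest::lillie.test(x),
                   error = function(e) list(statistic = NA, p.value = NA))
    data.frame(season = g, n = length(x),
               shapiro_W = unname(sw$statistic), shapiro_p = sw$p.value,
               lilliefors_D = unname(lf$statistic),
               lilliefors_p = lf$p.value)
  }))
  parametric <- all(normality$shapiro_p > alpha)

  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(pp) {
    a <- groups[[pp[1]]]; b <- groups[[pp[2]]]
    tst <- if (parametric) stats::t.test(a, b)
           else stats::wilcox.test(a, b, exact = FALSE)
    data.frame(group1 = pp[1], group2 = pp[2],
               statistic = unname(tst$statistic), p = tst$p.value,
               method = if (parametric) "t" else "mann-whitney")
  }))

  x_all <- unlist(groups, use.names = FALSE)
  g_all <- factor(rep(names(groups), vapply(groups, length, 0L)))
  omnibus <- if (length(groups) == 2L) {
    list(statistic = pairwise$statistic[1], p = pairwise$p[1],
         method = pairwise$method[1])
  } else if (parametric) {
    ow <- stats::oneway.test(x_all ~ g_all, var.equal = TRUE)
    list(statistic = unname(ow$statistic), p = ow$p.value, method = "anova")
  } else {
    kw <- stats::kruskal.test(x_all, g_all)
    list(statistic = unname(kw$statistic), p = kw$p.value,
         method = "kruskal-wallis")
  }

  structure(list(variable = variable,
                 route = if (parametric) "parametric" else "rank",
                 normality = normality, omnibus = omnibus,
                 pairwise = pairwise),
            class = "season_comparison")
}

#' @export
print.season_comparison <- function(x, ...) {
  cat(sprintf("<season_comparison> %s: %s route; omnibus %s = %.3g, p = %.3g\n",
              x$variable, x$route, x$omnibus$method, x$omnibus$statistic,
              x$omnibus$p))
  invisible(x)
}

#' Run the full association battery
#'
#' Convenience wrapper producing the battery's four tables: pooled
#' correlations, photoperiod-adjusted models, fully adjusted models for
#' the light metrics (with partial eta-squared), and demographic effects.
#' BH flags are applied across each table's family.
#'
#' @inheritParams simple_correlations
#' @param light_predictors light metrics entered one at a time in the
#'   adjusted models.
#' @return list with elements `correlations`, `photoperiod_adjusted`,
#'   `fully_adjusted`, `demographics`.
#' @export
associate_cohort <- function(cohort,
                             light_predictors = c(default_light_predictors(),
                                                  "melatonin_acrophase_h"),
                             outcomes = default_outcomes(),
                             fdr = 0.1, family = c("all", "per_outcome")) {
  family <- match.arg(family)
  corr <- simple_correlations(cohort,
                              predictors = c("photoperiod_h", light_predictors),
                              outcomes = outcomes, fdr = fdr, family = family)
  photo <- do.call(rbind, lapply(outcomes, function(out)
    do.call(rbind, lapply(light_predictors, function(pr)
      na_row_on_error(photoperiod_adjusted_model(cohort, out, pr),
                      out, pr, "photoperiod_adjusted")))))
  photo$p_rank_significant <- apply_family_flags(photo, fdr, family)
  full <- do.call(rbind, lapply(outcomes, function(out)
    do.call(rbind, lapply(light_predictors, function(pr)
      na_row_on_error(fully_adjusted_model(cohort, out, pr),
                      out, pr, "fully_adjusted", vif = TRUE)))))
  full$p_rank_significant <- apply_family_flags(full, fdr, family)
  demo <- demographics_table(cohort, outcomes)
  demo$p_rank_significant <- apply_family_flags(demo, fdr, family)
  list(correlations = corr, photoperiod_adjusted = photo,
       fully_adjusted = full, demographics = demo)
}

# battery tables degrade gracefully: a model that cannot be fitted on this
# cohort (e.g. a covariate-degenerate subset) contributes an NA row rather
# than aborting the remaining pairs
na_row_on_error <- function(expr, outcome, predictor, model, vif = FALSE) {
  tryCatch(expr, error = function(e) {
    row <- data.frame(outcome = outcome, predictor = predictor,
                      model = model, estimate = NA_real_,
                      variance_explained = NA_real_, p = NA_real_,
                      p_rank_significant = NA, n = 0L)
    if (vif) row$vif_warning <- NA
    row
  })
}
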