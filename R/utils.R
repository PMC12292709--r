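# Small shared helpers. Nothing here is exported.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators do not perturb user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stop("`seed` must be a single non-negative integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# wrap clock hours onto [0, 24)
wrap24 <- function(x) x %% 24

# signed circular difference a - b on the 24 h circle, in (-12, 12]
circ_diff_h <- function(a, b) {
  d <- (a - b) %% 24
  ifelse(d > 12, d - 24, d)
}

# column z-score; binary indicators are scaled to unit variance like any
# other predictor so standardized coefficients are comparable
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a zero-variance variable", call. = FALSE)
  (x - mean(x)) / s
}

# clock-like variables are treated as circular and unwrapped before
# modelling (see unwrap_clock)
is_circular_name <- function(name) {
  grepl("acrophase|onset", name)
}

# moment-matched log-normal draws (mean m, sd s on the raw scale)
rlnorm_ms <- function(n, m, s) {
  if (s <= 0) return(rep(m, n))
  sigma2 <- log(1 + (s / m)^2)
  stats::rlnorm(n, meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

fmt_signif <- function(x, digits = 6) {
  if (is.numeric(x)) signif(x, digits) else x
}
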