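# circalipid

Circadian light-exposure metrics and blood-lipid association modelling for
cohorts living under extreme seasonal photoperiods.

## The problem

At high latitudes the natural day length swings between < 1 h around the
winter solstice and > 23 h around the summer solstice. Wearable light
loggers show that what changes for residents is not only *how much* light
they receive but *when* it arrives and how strongly it contrasts between
day and night. This package implements an analysis chain for asking which
of those features — photoperiod duration, light timing, or light dynamic
range — predicts morning fasting blood lipids (TC, LDL-C, HDL-C, TG and
the TG/HDL ratio), together with a seeded synthetic cohort generator so
the whole chain can be exercised and tested without access to raw field
recordings.

It is aimed at chronobiologists and biostatisticians working with
per-minute actigraphy/light-logger exports, salivary melatonin profiles
and single-time-point lipid panels.

## Methods at the core

* **Cosinor rhythmometry.** For a per-minute light series the model
  `Y(t) = M + A cos(2π(t − φ)/24) + e(t)` is fitted by least squares on
  cosine/sine regressors: `M` (MESOR, rhythm-adjusted mean), `A`
  (amplitude) and `φ` (acrophase, clock time of the fitted peak), with the
  zero-amplitude F test on (2, n − 3) df.
* **Non-parametric endpoints.** M10/L5 — means over the 10 most- and 5
  least-exposed consecutive hours of the composite day (cyclic 1-min
  window scan) with their onsets; relative amplitude
  `RA = (M10 − L5)/(M10 + L5)`; and the normalized amplitude `NA = A/M`,
  an index of circadian light hygiene (large NA = strong day/night light
  contrast; small NA = weak daytime light and/or light at night).
* **Melatonin.** Consecutive-difference outlier filtering (removals at
  changes > 2 SD) and acrophase estimation by cosinor on irregular
  21-sample 24 h profiles.
* **Association battery.** Pooled Pearson correlations,
  photoperiod-adjusted OLS (photoperiod encoded 1/12/23 h for winter
  solstice / equinox / summer solstice), fully adjusted models
  (photoperiod + age + sex + indigeneity) reporting standardized β and
  Type III partial η², Benjamini–Hochberg FDR flags (q = 0.1), VIF
  screening, and normality-routed seasonal comparisons
  (Shapiro–Wilk/Lilliefors gate → t/ANOVA or Mann–Whitney/Kruskal–Wallis).
* **Correlation rhythmometry.** Correlations of a morning lipid with
  blue-light exposure in 48 consecutive 30-min clock epochs, BH masking of
  significant epochs, and a cosinor fit to the correlation curve r(t) —
  the acrophase of r(t) is the clock time at which the lipid–light
  association peaks.

The synthetic generator plants all of these structures (seasonal
calibration targets, standardized lipid effects, time-of-day association
peaks) so that every stage can be validated by parameter recovery.

## Worked example

```r
library(circalipid)

## one synthetic spring-equinox recording, and its endpoints
rec <- generate_light_series(season_profiles()["SE", ], seed = 7)
fit_cosinor(rec$blue)
#> <cosinor 24h> MESOR 37.27  amplitude 45.99  acrophase 12:08  F(2,10077) 3.85e+03  p 0
nonparametric_metrics(rec$blue)
#> <np_metrics> M10 73.13 @ 07.00h  L5 0.06882 @ 23.95h  RA 0.998  NA 1.234
```

The fitted MESOR (37.3 uW/cm2 of blue irradiance) is the rhythm-adjusted
24 h mean, the acrophase (12:08) says exposure peaks just after noon, and
NA = 1.23 indicates a healthy day/night contrast (L5, the darkest 5 h, is
essentially dark at 0.07 uW/cm2 starting 23:57).

```r
## a 27-subject x 3-season cohort with planted lipid effects
coh <- generate_cohort(27, seed = 42)
fully_adjusted_model(coh, "tg_hdl", "na")
#>   outcome predictor          model estimate variance_explained        p
#> 1  tg_hdl        na fully_adjusted   -0.376              0.185 9.25e-05

compare_seasons(coh, "na")
#> <season_comparison> na: parametric route; omnibus anova = 8.7, p = 0.000388
```

The fully adjusted model (photoperiod, age, sex, indigeneity as
covariates) recovers the planted negative association between the
normalized amplitude of blue-light exposure and the TG/HDL ratio:
standardized β = −0.38, partial η² = 0.185 — a larger daily light dynamic
range goes with a lower cardiometabolic risk proxy, independent of
photoperiod.

The full pipeline (`simulate → metrics → melatonin → associate → rhythm`)
writes its tables and a reproducibility manifest with:

```r
run_pipeline(default_config(), out_dir = "circalipid_out")
```

or from a shell, `Rscript inst/cli/circalipid.R run --seed 1 --out-dir out`.

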