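---
title: "Circadian light exposure and blood lipids: models, generator design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian light exposure and blood lipids: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circalipid)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, what the synthetic cohort generator does and
does not emulate, and the numerical decisions taken where the underlying
methodology left room.

## 1. The measurement model

A wearable light logger records white light (lux) and its blue spectral
component (uW/cm2) every minute over seven days. Two families of
endpoints summarise such a series.

**Parametric (cosinor).** The single-component cosinor

$$Y(t) = M + A\cos\!\left(\frac{2\pi (t - \varphi)}{24}\right) + e(t)$$

is linear in $(M, \beta_c, \beta_s)$ after writing the cosine in its
cos/sin basis, so `fit_cosinor()` solves it by ordinary least squares:
$A = \sqrt{\beta_c^2+\beta_s^2}$, $\varphi = \operatorname{atan2}(\beta_s,
\beta_c)\cdot 24/2\pi$. The acrophase is reported as the *local clock time
of the fitted peak* (not in negative degrees), matching how seasonal
summaries are usually tabulated. The zero-amplitude test is the classical
F statistic on 2 numerator degrees of freedom. Assumptions: a stable
24 h period over the record, additive noise, and pooling of all days into
one fit (single-cosinor practice; the fit uses the full per-minute record,
not the composite day).

**Non-parametric.** `nonparametric_metrics()` computes M10 and L5 — the
mean level over the 10 most-exposed and 5 least-exposed *consecutive*
hours — on the composite day (per-clock-minute mean across days), by an
exhaustive cyclic scan over all 1440 window starts at 1-minute
resolution. Ties are broken toward the earliest clock onset. The relative
amplitude $RA = (M10-L5)/(M10+L5)$ lies in $[0,1]$; the normalized
amplitude $NA = A/M$ of the blue channel is the package's circadian light
hygiene index. Whether a composite-day or per-day window basis is the
"standard" is genuinely ambiguous across actigraphy software; the
composite basis is the default here (more robust on 7-day records with
missingness), with `basis = "per_day"` available.

**Missingness policy.** Minutes missing in at most 20% of a day are
ignored in composite averaging; days missing more are dropped; fewer than
`min(3, n_days)` surviving days is an error. Alignment padding from an
off-midnight recording start is *not* counted as missingness.

## 2. Melatonin profiles

Salivary melatonin is sampled ~21 times over 24 h, densest before and
during sleep. Quality control (`qc_filter()`) removes non-finite or
negative values and "extreme outliers", operationalised as changes
exceeding 2 standard deviations between consecutive samples. Two details
are deliberate choices:

* the SD is computed **once** over all consecutive differences of the raw
  profile, and flagging is a **single deterministic pass** comparing each
  sample against its most recent *accepted* predecessor (no SD
  re-estimation after removals, which would make the result
  order-sensitive);
* the threshold is stored with the profile, so repeating the filter is a
  no-op — the filter is idempotent by construction.

A consequence of the 2-SD rule is that a sample flagged at the start of a
steep nocturnal flank can strand the comparison anchor and cascade; with
realistic noise a small fraction of generated profiles lose enough
samples to become unusable (< 4 valid samples, or a time span too short
to identify a 24 h fit). These profiles are treated as missing, exactly as a
failed field collection would be, and all melatonin models run on the
complete-case subset.

`melatonin_acrophase()` fits the same 24 h cosinor on the irregular
sampling times (raw concentrations; no log transform by default since
none is standard for this assay range) and requires a span above 12 h to
avoid an aliased phase.

## 3. The association battery

All subject-seasons are pooled as independent rows — the same
simplification the emulated "overall data" analyses make; no
subject-level random effect is fitted. Models:

* `simple_correlations()` — Pearson r per (predictor, outcome) pair;
* `photoperiod_adjusted_model()` — OLS of the z-scored outcome on the
  z-scored predictor plus z-scored photoperiod (encoded 1 h, 12 h, 23 h
  for the three seasons);
* `fully_adjusted_model()` — adds age, sex (female = 0/male = 1) and
  indigeneity (native = 0/non-native = 1), reporting the predictor's
  standardized β and its Type III partial
  $\eta^2 = SS_{pred}/(SS_{pred}+SS_{res})$, computed as the drop-one
  residual-sum-of-squares difference (identical to Type III here because
  every term enters once);
* `bh_adjust()` — the classic Benjamini–Hochberg step-up rule at
  q = 0.1, applied across the whole predictor-by-outcome family of each
  table by default (`family = "per_outcome"` is available);
* `vif()` — auxiliary-regression variance inflation factors; any value
  above the configured ceiling (default 5) attaches a warning flag;
* `compare_seasons()` — Shapiro–Wilk and Lilliefors screening per group;
  Shapiro–Wilk is decisive for routing (parametric t/ANOVA vs
  Mann–Whitney/Kruskal–Wallis), and both statistics are reported.

**Circular predictors.** Acrophases and window onsets live on the 24 h
circle; nocturnal onsets straddle midnight. `unwrap_clock()` maps them to
a continuous scale centred on their circular mean (signed differences in
(−12, 12] h) before standardization, for both generation and analysis, so
"earlier" and "later" have a consistent linear meaning.

**Standardization.** All predictors, including binary indicators, are
z-scored on the analysis sample, so standardized βs are comparable across
predictors. p = 0 from a numerically perfect fit is accepted by the BH
step (trivially significant) rather than rejected.

## 4. Correlation rhythmometry

For each lipid the exposure matrix holds each subject-season's composite
mean blue irradiance in 48 consecutive 30-min clock epochs
(`epoch_exposure_matrix()`). Per-epoch Pearson correlations with the
morning lipid give the curve r(t); `significant_epoch_mask()` applies BH
within the 48-epoch family per lipid (not pooled across lipids), and
`fit_r_rhythm()` fits a 24 h cosinor to the (epoch centre, r) points —
epoch centres, not starts, are the time coordinate, which is symmetric
and unbiased. Undefined epochs (zero exposure variance) are excluded from
both the BH family and the cosinor fit rather than imputed. The cosinor
is fitted to raw r values by default; `fisher_z = TRUE` fits
variance-stabilised atanh(r) instead.

## 5. What the generator emulates

`generate_cohort()` simulates the full study design: subjects observed
once per season (winter solstice, spring equinox, summer solstice),
demographics matched to the emulated cohort's composition (25% male, 70%
non-native, ages 18–59), and per-minute light recordings.

**Light series.** Each subject-season draws latent endpoints from the
season's calibration profile (`season_profiles()`): MESOR and the
light-at-night level log-normally (light is non-negative and
right-skewed — the summer-solstice SDs exceed their means), normalized
amplitude and clock times normally. The waveform is a daytime plateau
over a weakly modulated nocturnal baseline:

* The bright-window width W and height h are *solved* from the drawn
  MESOR and amplitude via the rectangle's Fourier fundamental
  ($x/(2\sin x) = (M-b)/A$ with $x = \pi W/24$), so a cosinor fit of the
  noiseless waveform returns the planted triple exactly. The solved
  widths (≈ 13 h in winter, ≈ 10 h in summer) exceed the natural
  photoperiod, reflecting artificial lighting — and they reproduce the
  observed geometry: the implied M10 onsets fall in the 07:45–09:15
  range, consistent with the tabulated seasonal onsets.
* The nocturnal baseline carries a shallow cosine trough (depth 0.3)
  whose centre plants the L5 onset; the baseline level is scaled so the
  composite L5 matches the drawn light-at-night target. The plateau's
  fundamental is corrected for the baseline modulation vectorially, so
  the planted cosinor parameters remain exact. When a drawn trough abuts
  a narrow bright window the planted L5 becomes approximate — a geometric
  inevitability, left as is.
* Minute noise is multiplicative log-normal with unit mean
  (`noise_sigma = 0.6`), preserving calibration targets in expectation.
  White lux is a fixed multiple (7) of blue irradiance; only blue drives
  the headline metrics.
* Each subject keeps persistent acrophase and NA offsets across seasons
  (SD 0.3 h and 0.05), a small within-subject stability term.

**Lipids.** Latent z-scored outcomes are
$y = \sum_k \beta_k z(x_k) + \varepsilon$ over the cohort's realized
(z-scored, circularly unwrapped) predictor columns, with planted
standardized effects taken from the fully adjusted effect sizes of the
emulated analysis (`effect_spec()`): nocturnal L5 raising TC/LDL-C/TG, an
earlier blue-light acrophase and larger NA raising HDL-C, NA lowering TG,
male sex lowering HDL-C, non-native status raising TG, age raising
TC/LDL-C, and a later melatonin acrophase raising TG. Residual SD is
$\sqrt{1-\sum\beta_k^2}$. Concentrations are mapped *linearly* onto
generic adult reference scales (TC 5.0 ± 1.0, LDL-C 3.0 ± 0.9, HDL-C
1.40 ± 0.35, TG 1.3 ± 0.6 mmol/L; floored at 5% of the mean) — these
marginals are invented defaults, as no cohort lipid summaries are
available to calibrate against. A linear map was chosen over a log-normal
one so that planted standardized effects transfer exactly to the
concentration scale; with a log-normal map, heavy-tailed predictors
(L5 especially) interact with the curvature of the exponential and bias
the recovered coefficients. The TG/HDL ratio is always computed
as TG/HDL-C, never generated — its associations (e.g. with NA) *emerge*
from the planted TG and HDL-C effects, and emerge close to the published
ratio coefficient, which is a satisfying internal-consistency check of
the planted effect set. The timing effect on HDL-C is carried by the
acrophase alone; the M10-onset coefficient is not planted additionally,
because the two are geometrically collinear in the generator and planting
both would confound single-predictor recovery.

**Melatonin.** Profiles are cosines (mesor 12, amplitude 10 pg/mL,
additive noise SD 2) sampled on a 21-point template dense between ~20:30
and ~08:15 with sparse daytime samples spaced to track the flat trough.
The template is shifted by each subject's phase, mirroring personalized
sleep-diary-based schedules; the exact protocol times are unpublished, so
the template is configurable. Latent melatonin acrophases are entrained
to the subject's blue-light acrophase (slope 0.6) around a 03:30 mean.

**Two generation methods.** `method = "series"` builds every per-minute
recording and estimates all endpoints from it exactly as for real data;
`method = "analytic"` emits the latent endpoints directly via the
closed-form window geometry. The two agree (correlations > 0.95 on all
endpoints in the suite); large parameter-recovery simulations use the
analytic path for speed, and all calibration checks use the series path.

**The rhythm scenario.** `generate_rhythm_cohort()` plants time-localised
associations: each subject's exposure is tilted multiplicatively by two
standard-normal scores through cosine weights peaking at the HDL-C
(08:55) and TG (23:38) target times, on top of a per-epoch "habit"
component (SD 0.45) that is constant across days so it survives composite
averaging. Lipids are linear in the scores. The resulting r(t) is close
to a cosine with its maximum at the planted peak; the planted circular
separation of the two peaks is 9.28 h, the day/night antiphase pattern.
The default tilt strength (0.15) and habit SD were chosen once to give
r-curves of moderate amplitude, comparable to published
epoch-correlation curves; at 200 subjects the suite verifies that the
fitted r-rhythm acrophase recovers the planted peak to well within
three quarters of an hour (a small systematic component comes from the
time-varying exposure variance in the denominator of r(t)).

**What passing tests do *not* show about real data.** The generator's
days are stationary (no weekday/weekend structure, no weather), its
noise is temporally white, lipid panels ignore the TC ≈ LDL + HDL + TG/2.2
constraint, melatonin is a pure cosine rather than the flat-low/steep-peak
shape of real profiles, and all subject-seasons are exchangeable rows.
Recovery of planted effects therefore validates the estimators and the
plumbing, not the biological claims; with pooled rows the models also
inherit the emulated analysis's simplification of treating repeated
subjects as independent.

## 6. Numerical choices and degenerate inputs

* Acrophase is undefined (flagged, `NA`) when the fitted amplitude is
  below $10^{-9}\max(|M|,1)$; a constant series yields F = 0, p = 1.
* The window scan uses cumulative sums on the doubled composite day;
  levels agree with a literal scan to the last floating-point ulp and
  window *selection* is exactly identical.
* Circular means with resultant length below $10^{-9}$ are flagged
  undefined (perfectly symmetric inputs).
* `solve_window()` clamps its mean-to-amplitude ratio into
  (0.505, 10): ratios at the lower bound correspond to the geometric
  limit where no non-negative plateau waveform can realise the requested
  normalized amplitude over the drawn baseline (NA < 2 is an intrinsic
  bound for such waveforms); drawn NA values are truncated to
  [0.05, 1.85].
* Covariates constant on an analysis subset are dropped from adjusted
  models (non-identifiable); a constant *focal* predictor is an error.
  Battery tables degrade to NA rows for unfittable pairs instead of
  aborting the remaining pairs.
* Fully adjusted models require ≥ 8 complete rows, photoperiod-adjusted
  ≥ 5, correlations ≥ 4 — below that they refuse with an
  "insufficient df" error.
* All TSV output is written with 6 significant digits and fixed column
  order; timestamps are naive local clock (the emulated region observes
  no daylight saving time), so no timezone arithmetic is performed.

## 7. Problem sizes used by the test suite

The suite validates cosinor exactness on noiseless 7-day series; window
oracles on 100 random series; planted-β recovery on 100 cohorts of 500
subjects × 3 seasons via the analytic path; calibration on 200-subject
seasonal cohorts via the series path; rhythm recovery on one 200-subject
minute-resolution cohort plus 300 null replicates at 40 subjects; and
pipeline determinism end-to-end at 27 subjects × 3 seasons, the emulated
design size. These sizes make the Monte-Carlo error a small fraction of
each tolerance while keeping the default test run fast.

## 8. Known limitations

* Pooled subject-season rows understate uncertainty for within-subject
  contrasts; a mixed-effects extension would be the natural next step.
* The 2-SD melatonin QC rule can cascade on steep flanks (Section 2);
  an alternative robust rule (e.g. median absolute deviation of
  differences) is deliberately not substituted, to keep the documented
  behaviour.
* The amplitude summaries of the seasonal calibration profiles are
  honoured implicitly (amplitude = NA × MESOR); their tabulated SDs are
  not separately enforced.
* The white-lux channel is a fixed multiple of blue, so white-channel
  metrics are scaled copies; only the blue channel carries independent
  information, matching the analysis's emphasis.
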