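---
title: "Models and methods: greenness covariates, the binomial productivity index, and the constrained Barker survival likelihood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalgreen)
```

`vitalgreen` estimates how rainfall-driven vegetation greenness relates to
two vital rates of resident landbirds sampled by constant-effort mist
netting: the productivity index (proportion of young in the aged catch)
and adult apparent survival. This vignette is the package's own account of
the models, their assumptions, the tunable parameters, and the numerical
and design choices behind the implementation.

## Study design the package assumes

A small set of banding stations (six by default) is operated every year in
a fixed sampling window, 11 April–19 July. Captures inside the window are
the *primary-period* data; captures between windows (extended sampling in
some years) are *between-period* detections. Monthly station-scale EVI
(unitless, roughly −0.2–1) comes from a greenness raster — station values
can be extracted from a grid by `bilinear_extract()` — and monthly
rainfall totals (mm) from a single weather station.

## Seasonal covariates

`build_covariates()` reduces monthly EVI to the station-year table both
demographic models consume:

* `evi_mn` — the station's mean over every monthly value supplied (pass
  exactly the span the mean should cover; the generator supplies the
  pre-study year through the last study year, and this column captures
  persistent habitat structure);
* `evi_w`, `evi_d` — year-specific means of the late wet (Sep–Nov) and
  late dry (Mar–May) season months;
* `evi_w_dev`, `evi_d_dev` — those means minus the station's across-year
  seasonal average: "relative greenness", which isolates temporal
  variation from persistent station differences. Per station these sum to
  zero over the table's years by construction;
* standardized copies (`*_z`, pooled mean 0/SD 1 over the station-year
  rows, SD with the n−1 divisor — the conventional sample SD). The
  mean/SD pairs are stored on the table (`attr(, "scalers")`) so
  predictions can transform new values identically.

Wet-season values are stored under the calendar year of their Sep–Nov
months. The productivity design joins its wet-season terms on the
*previous* year at design-matrix time; keeping the table year-unambiguous
and doing the lag at the join avoids two bookkeeping conventions for one
column. Because the models need the pre-study wet season, the covariate
table is built from the year before the first study year onward; the
deviation means therefore average one more year than the study span, a
deliberate simplification that keeps every row complete.

The rainfall–greenness link is checked by `fit_rain_evi()`, an OLS of EVI
on log rainfall lagged one month (greenness composites are dated at the
start of the month, rain totals at the end, so Feb–Apr rain pairs with the
Mar–May greenness season and Aug–Oct with Sep–Nov). The operation accepts
any paired sample, so seasonal means and monthly series use the same code
path.

## The binomial productivity index

Counts of year-unique young (`N^Y`) and adult (`N^A`) individuals aged in
the window give

$$N^Y_{st} \mid (N^Y_{st}+N^A_{st}) \sim \mathrm{Bin}\!\left(N^Y_{st}+N^A_{st},\; p[Y]_{st}\right),
\qquad \mathrm{logit}(p[Y]_{st}) = x_{st}'\beta .$$

Window membership is by calendar date, closed on both ends. An individual
aged young at any window capture of a year counts as young; a
young-and-adult conflict within one window is a data error resolved to
young with a warning. Individuals that died in nets are retained here (the
exclusion applies to the survival analysis, where capture must not alter
fate); unknown-age individuals are dropped.

The prior-effort covariate `pr_ef = log(1 + net-hours)` sums effort
strictly between the previous window's end and the current window's start;
the first study year has no prior window and gets 0. It corrects for net
avoidance induced by netting before the window and is standardized over
the analysis rows like the EVI terms.

The candidate set crosses eight greenness structures — none; `evi_mn`;
lagged wet mean; dry mean; lagged wet deviation; dry deviation; additive
deviations; deviations plus interaction — with presence/absence of
`pr_ef`, giving 16 models. The wet and dry seasonal means never co-occur
(they are strongly correlated in data of this design), and the interaction
requires both deviation main effects. The exact membership of the 16-model
set is a design choice of this package: the constraints above admit more
than one grid, and this one respects all of them.

Fitting is Newton–Raphson (equivalently iteratively reweighted least
squares) with step-halving, from zero starts; `stats::glm` is used in the
test suite as an independent oracle, never as the implementation. The
log-likelihood keeps the binomial coefficient so AICc is comparable across
any model set fit to the same rows. Separation (any |coefficient| > 15 on
the logit scale) or failure to converge in 100 iterations clears the
`converged` flag, and such fits are excluded from Akaike-weight
normalization rather than silently ranked.

AICc needs an effective sample size: the default is the total number of
binomial trials, `n_eff = Σ(N^Y + N^A)`, the standard choice for grouped
logistic models; the station-year row count is available via
`n_eff_convention = "rows"` for sensitivity analysis.

## The constrained Barker survival likelihood

Encounter histories condition on the first adult window capture (release).
For each interval between primary periods, given alive at period *t*:

* survive (probability `S_st`) and be detected between periods with
  probability `R`, then be recaptured at *t*+1 with probability `p_{t+1}`;
* or die (1 − `S_st`), with a between-period detection before death with
  probability `R'`, after which no detection is ever possible.

Fixed by design: site fidelity `F = 1` and return `F' = 0` (captures all
occur on the study areas — a cross-station recapture is rejected with an
error rather than silently reassigned), dead recovery `r = 0` (no dead
recoveries), and `R = R' = 0` on *masked* intervals with no between-period
effort (by default the first interval). `R` and `R'` are single shared
parameters across the unmasked intervals; `p` is time-constant or
year-specific; `S` is logit-linear in station-interval covariates. The
parameter count `K` is the number of estimated quantities: S coefficients,
1 or T−1 recapture logits, plus `R` and `R'` when any interval is
unmasked — so the additive-deviation model with year-specific `p` over
five periods has K = 3 + 4 + 2 = 9.

The likelihood is evaluated by backward recursion over the alive/dead
process, vectorized across histories collapsed to unique
`(station, f, y, z)` patterns with multiplicities (collapsing changes
nothing — the tests verify identical log-likelihood and MLEs against
uncollapsed data). A between-period detection recorded on a masked
interval is a data/model conflict and errors out rather than returning a
zero likelihood.

Two structural properties anchor the implementation and are enforced in
the test suite: history probabilities over all possible completions of a
release sum to 1 (brute-force enumeration for T ≤ 4 across a parameter
grid, to 1e−10), and with `R = R' = 0` everywhere the likelihood equals
the classical Cormack–Jolly–Seber likelihood, checked against an
independent chi-recursion implementation both as a likelihood identity
(1e−8) and at the MLE (1e−4).

### Covariate timing for survival intervals

An interval runs spring-to-spring, so it contains one wet season and ends
in one dry season. For the interval from year *t* to *t*+1, `evi_w` terms
use the wet season of calendar year *t* (inside the interval) and `evi_d`
terms the dry season of year *t*+1 (ending at recapture); deviations
follow the same convention. The mapping of calendar seasons to intervals
is genuinely open in this design — both seasons fall inside the interval —
and this choice uses, for each season, the occurrence actually spanned by
the interval. Between-period captures that precede a year's window (e.g. a
February capture) belong to the preceding interval, which is the only
interval they can fall in.

### Optimization and uncertainty

Maximization is quasi-Newton (BFGS) on the unconstrained link scale from
all-zero starts (every probability 0.5), with restarts from ±1
perturbations when convergence fails; relative tolerance 1e−12, at most
500 iterations. Standard errors come from the inverse numerical Hessian at
the optimum; a singular Hessian leaves SEs `NA` but keeps the fit, flagged.
Predictions back-transform `x'β ± z·sqrt(x'Vx)` from the logit scale, so
intervals always lie inside (0, 1); requesting a standardized covariate
beyond ±4 SD triggers an extrapolation warning, not an error. The AICc
effective sample size is the number of released individuals, the common
convention for live-encounter models.

## Model comparison

`aicc()` implements `−2ℓ + 2K + 2K(K+1)/(n_eff − K − 1)` and
`akaike_weights()` the normalized evidence `exp(−Δ_i/2)`. Non-converged or
separated fits are listed at the bottom of the model table with `NA`
weight and excluded from normalization, so reported weights are a proper
distribution over trustworthy models. No model averaging or
overdispersion (quasi-AICc) adjustment is provided.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults encode the study conditions the package is built
around, chosen once as a realistic tropical-island banding program:

| parameter | default | rationale |
|---|---|---|
| stations × years | 6 × (2008–2012) | multi-station five-year design |
| rainfall | lognormal, monthly log-means peaking Jul–Nov (~65–310 mm median), log-SD 0.4 | strongly seasonal wet-season regime with realistic inter-annual spread |
| EVI response | 0.08 per log-mm, saturating at 350 mm, noise SD 0.02 | greenness tracks lagged rainfall but flattens at the highest rainfall |
| station baselines | 0.01–0.20 offsets | monthly mean EVI spanning ~0.41–0.60 across stations |
| survival | logit(0.6) intercept; +0.5 (dry), −0.5 (wet) per SD of relative greenness | moderate tropical passerine survival with opposing seasonal effects |
| recapture | 0.40 → 0.16 across years | net avoidance accumulating over a study |
| between-period detection | R = 0.35, R' = 0.10; first interval masked | substantial supplemental captures once extended sampling starts |
| productivity | logit-scale (−1.15, 0.73, 0.28, 0.46, 0.41) for intercept, `pr_ef`, wet dev, dry dev, interaction | young fraction near 0.24 responding strongly to relative greenness |
| recruits / aged totals | 36 and 60 per station-year | catch sizes of a common focal species |

Recruitment is exogenous: new marked individuals enter only at their first
capture, a fixed number per station-year, mirroring the analysis
likelihood's conditioning on release (the feedback from productivity to
next-year recruitment is deliberately not modeled). Individuals are young
in their recruitment year with the true productivity probability and adult
thereafter; since the survival analysis conditions on the first adult
window capture and the post-release process is age-invariant here,
recovery of survival parameters is unaffected. Between-period detection is
at most one event per interval (the likelihood's data model); real-world
repeat captures in an interval would collapse to one. Capture dates are
uniform within their window or interval — only window membership matters
downstream. Effort is deterministic: ten 54-net-hour days per window and
one such day per month between windows (except masked intervals).

Not emulated: spatial autocorrelation among stations, individual
heterogeneity in survival or detection, temporary emigration, dead
recoveries, multi-species communities, or missing months. Passing
parameter-recovery tests on these data therefore demonstrates correctness
of the estimator under its own assumptions, not robustness to the
violations real data bring.

All randomness flows from one integer seed; each generator stage derives
its own sub-seed, so stages rerun independently and identical
configurations are bit-identical.

## Numerical choices and degenerate inputs

* Logistic quantities use `plogis`/`qlogis`; the binomial log-likelihood
  uses a guarded `log(1 + exp(x))` to avoid overflow.
* Zero-probability histories make the negative log-likelihood return a
  large finite penalty (1e10) so line searches recover rather than crash.
* A release in the final period contributes likelihood 1 and carries no
  information; such histories are retained in counts.
* Rank-deficient productivity designs error immediately; a degenerate
  (zero) covariate SD standardizes to zeros rather than dividing by zero.
* Dates parse strictly as ISO-8601; unparseable dates error by row count.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the recovery studies at the
package's chosen sizes: 100 simulated survival datasets (six stations,
five periods, 100 releases per station-year — 500 per station overall)
for coefficient bias and Wald coverage; 500 (tests) or 100 (script)
productivity tables of ~100 aged birds per station-year; 200 (tests) or
100 (script) replicates of the 16-model AICc race at totals of 200; and
50,000 released individuals over three periods for the
generator-versus-likelihood goodness-of-fit comparison. These sizes make
Monte-Carlo noise small relative to the asserted tolerances while keeping
a full run inside a few minutes on one CPU.

## Known limitations

* Apparent survival equals true survival only under the fidelity
  constraint `F = 1`; permanent emigration is confounded with mortality.
* `R` and `R'` are shared across unmasked intervals; interval-specific
  between-period detection is not estimable in this design and not
  offered.
* No goodness-of-fit/overdispersion machinery (e.g. median-ĉ style
  procedures) is included; the package's correctness checks are
  normalization, reduction and recovery properties on synthetic data.
* The 16-model grids are one defensible reconstruction of the candidate
  sets; alternative grids satisfying the same constraints exist and can be
  passed explicitly to the fitting functions.
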