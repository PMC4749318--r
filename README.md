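# vitalgreen

Linking landbird vital rates to rainfall and vegetation greenness.

`vitalgreen` implements the full inference chain used to ask how seasonal
rainfall and remote-sensed vegetation greenness (the Enhanced Vegetation
Index, EVI) drive the demography of resident landbirds monitored by
constant-effort mist netting — the setting typical of small tropical
islands, where a handful of banding stations is sampled in a fixed annual
window over several years and most rain falls in a distinct wet season. It
is aimed at population ecologists working with banding data plus monthly
greenness and rainfall series.

Three linked analyses are provided:

1. **Seasonal greenness covariates and the rainfall–EVI regression.**
   Monthly station-scale EVI is reduced to the covariates the demographic
   models use: the station's across-span monthly mean (`evi.mn_s`),
   year-specific late wet (Sep–Nov) and late dry (Mar–May) season means
   (`evi.w_st`, `evi.d_st`), and their deviations from station-specific
   across-year seasonal means (`evi.w.dev_st`, `evi.d.dev_st` — "relative
   greenness"), all standardized. EVI is regressed on one-month-lagged
   log rainfall by OLS.

2. **A binomial productivity index.** With `N^Y_st` young and `N^A_st`
   adult year-unique individuals aged in the fixed window (11 Apr–19 Jul),

   `N^Y_st | (N^Y_st + N^A_st) ~ Bin(N^Y_st + N^A_st, p[Y]_st)`,
   `logit(p[Y]_st) = β0 + β1 pr.ef_st + Σ β_i evi_i`,

   where `pr.ef_st = log(1 + net-hours between windows)` corrects for net
   avoidance. Sixteen candidate covariate structures are fit by
   Newton–Raphson maximum likelihood and compared by AICc and Akaike
   weights.

3. **Adult apparent survival under a constrained Barker model.** Encounter
   histories combine within-window live recaptures (`y_t`, probability
   `p_t`) with between-window "resighting" captures (`z_t`): probability
   `R` if the bird survived the interval, `R'` if it died during it
   (detection preceding death). Site fidelity `F = 1`, return rate
   `F' = 0`, and dead recovery `r = 0` are fixed by design; `R = R' = 0`
   on intervals without between-period effort. Survival `S_st` is
   logit-linear in the station-interval greenness covariates; sixteen
   `S` × `p` structures are ranked by AICc. With `R = R' = 0` everywhere
   the likelihood reduces to Cormack–Jolly–Seber, which the tests exploit
   as an independent cross-check.

Because band-level field data of this kind are rarely redistributable, the
package ships a first-class synthetic-data generator (`sim_config()`,
`run_simulate()`) that reproduces the statistical structure of all four
input streams — seasonal lognormal rainfall, EVI responding to lagged log
rainfall with saturation, capture/effort records drawn from the constrained
Barker process, and binomial age counts — together with every true
parameter value, so the whole chain is testable end to end.

## Worked example

```r
library(vitalgreen)

cfg <- sim_config(seed = 42)                 # the default study conditions
sim <- run_simulate(cfg, tempfile())         # writes CSVs + truth JSON
report <- run_all(sim$captures, sim$effort, sim$evi, sim$rainfall)
report
#> Rainfall-greenness-demography analysis report
#>   years: 2008-2012
#>   EVI ~ log(rain): slope 0.0793 (SE 0.0114)
#>   top productivity model: pr_ef + evi_w_dev_prev + evi_d_dev + evi_w_dev_prev:evi_d_dev (w = 0.97)
#>   top survival model:     S(evi_w_dev + evi_d_dev) p(year) (w = 0.52)
```

The generator's true values here are an EVI–rainfall slope of 0.08, a
productivity model containing the prior-effort term and the seasonal
deviation interaction, and additive survival effects of −0.5 (wet) and
+0.5 (dry) per SD of relative greenness with year-varying recapture — all
of which the analysis identifies. The survival model table and top-model
coefficients:

```r
tibble::as_tibble(report$survival)[1:4, c("model", "K", "AICc", "delta_AICc", "weight")]
#>   model                                K  AICc delta_AICc weight
#> 1 S(evi_w_dev + evi_d_dev) p(year)     9 2254.       0    0.521
#> 2 S(evi_w_dev * evi_d_dev) p(year)    10 2255.       1.10 0.300
#> 3 S(evi_w_dev * evi_d_dev) p(.)        7 2258.       4.14 0.0657
#> 4 S(evi_d_dev) p(year)                 8 2259.       4.57 0.0530

tidy(report$survival_top)[1:3, 1:3]
#>   term          estimate std.error
#> 1 S:(Intercept)    0.347     0.154
#> 2 S:evi_w_dev     -0.343     0.143
#> 3 S:evi_d_dev      0.460     0.161
```

Predicted survival against relative dry-season greenness (delta-method
95% intervals, back-transformed from the logit scale):

```r
predict_survival(report$survival_top, tibble::tibble(evi_d_dev = c(-1, 0, 1), evi_w_dev = 0))
#>   evi_d_dev evi_w_dev estimate conf_low conf_high
#> 1        -1         0    0.472    0.398     0.547
#> 2         0         0    0.586    0.512     0.657
#> 3         1         0    0.692    0.567     0.793
```

`autoplot()` methods draw the standard prediction surfaces
(`autoplot(report$survival_top)`, `autoplot(report$productivity_top)`)
and model-weight charts (`autoplot(report$survival)`); `tidy()` and
`glance()` expose every fit broom-style.

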