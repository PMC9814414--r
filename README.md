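# phenocap

Capped thermal-time models for tundra flowering phenology.

Growing-degree-day (GDD) models assume every degree of warmth above 0 °C
advances plant development proportionally. Cold-adapted plants may instead
have a **maximum limiting temperature**: hours hotter than a cap `T_max`
advance phenology no further than the cap itself. `phenocap` is for
phenologists and climate-change ecologists who have hourly canopy
temperatures, snowmelt dates and repeated flower censuses, and want to ask:
*is there a temperature above which flowering stops responding, and does a
capped model predict better — particularly under experimental warming?*

## The model

Forcing accumulated from snowmelt, in degree-days:

```
GDD:                 f(T) = 0            if snow-covered or T ≤ 0
                            T / 24       otherwise
GDD_max(T_max):      f(T) = 0            if snow-covered or T ≤ 0
                            min(T, T_max) / 24   otherwise
```

Seasonal flower counts per census are fit as a penalized-spline Poisson
GAM with a log intercensus-interval offset and year random intercepts,

```
count_t ~ Poisson(mu_t),   log mu_t = s(F(mid_t)) + log(Δt) + b_year ,
```

by maximum likelihood (`mgcv`). The cap is estimated by refitting over a
grid of `T_max` values and taking the AIC minimum; a species is *saturating*
when the best capped model beats uncapped GDD by ≥ 2 AIC units and the cap
lies within the 95th percentile of observed snow-free summer temperatures.
Uncertainty comes from a leave-one-year-out jackknife. Predictive skill of
DOY / GDD / GDD_max models is compared by RMSE of seasonal flowering
percentages, with models trained on ambient plots and evaluated on both
ambient and experimentally warmed plots. A synthetic-data generator
(hourly temperatures with diurnal cycle and AR(1) noise, passive-warming
treatment that inflates daily maxima, snowmelt dates, plot-level censuses
from a capped thermal response with known true `T_max`) provides ground
truth for every stage.

## Worked example

```r
library(phenocap)
out <- run_pipeline(outdir = "pheno-demo", seed = 1)
out$estimates
```

```
           species    location true_tmax best_threshold median_threshold
1 capped_responder high_arctic         5            6.0            6.00
2 linear_responder high_arctic        NA           12.5           13.75
  min_threshold max_threshold saturating meaningful temp_q95
1            3             6       TRUE       TRUE 10.60407
2           12            15      FALSE      FALSE 10.60407
```

Two synthetic species are simulated at a cold high-Arctic site (8 years, 24
plots, weekly censuses) and analysed end to end. The species generated with
a true 5 °C cap is estimated at 6.0 °C (within one 0.5 °C grid step of
truth; jackknife range 3–6 °C over leave-one-year-out refits), classified
saturating, and the estimate is *meaningful* — the whole range sits below
the 10.6 °C that bounds 95% of snow-free summer hourly temperatures. The
linear responder's best grid value drifts to the top of the scan and is
correctly left non-saturating. `out$rmse_summary` shows the predictive
ordering (median percentage-point RMSE of seasonal flowering curves; smaller
is better): GDD_max 1.53 beats GDD 1.93 beats DOY 7.99 on ambient plots, and
the GDD_max advantage widens on warmed plots (1.42 vs 3.46 vs 8.92) —
passive warming inflates daily maxima, exactly the hours a cap discounts. Every artifact (CSVs, AIC profiles, a JSON manifest with
checksums and seeds) is written to `outdir`; the run is bit-reproducible
from the seed. Lower-level entry points (`accumulate_forcing()`,
`census_to_flowers()`, `fit_phenology_gam()`, `scan_thresholds()`,
`jackknife_threshold()`, `compare_forcing_models()`) expose each stage for
real data; see the vignette in `vignettes/capped-thermal-time.Rmd`.

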