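# seasonsync

Seasonal variation in hospitalization outcomes, and how to keep it from
confounding pre/post telemonitoring comparisons.

Hospital admissions and length of stay (LOS) in chronically ill cohorts are
strongly seasonal — winter–spring excesses in temperate Australia, wet/dry
contrasts in the subtropics — and patients in home-telemonitoring trials are
recruited over many months, so each patient's post-intervention period
samples the seasonal cycle at a different phase. `seasonsync` implements,
for biostatisticians evaluating such trials:

* **Baseline detrending**: per climate zone, monthly outcome sums over a
  multi-year pre-intervention window are fitted by OLS on the month index
  (`fit_linear_trend()`), giving the secular "aging" baseline with
  R², adjusted R², RSS, RMSE and 95% prediction bounds.
* **Seasonal profiles**: percentage deviations from the baseline,
  d_t = 100·(y_t − ŷ_t)/ŷ_t, averaged per calendar month across years
  (`percent_deviation()`, `seasonal_profile()`, `peak_deviation()`).
* **The synchronized profile**: the expected seasonal deviation experienced
  i months after each patient's intervention commencement,

      S_p(i) = Σ_k P_zone(k)[ ((c_k + i − 2) mod 12) + 1 ] / n_i ,

  pooled over patients k still monitored at month i with commencement
  months c_k (`synchronized_profile()`, `max_sync_deviation()`). Spreading
  commencements over the recruitment window makes individual seasonal
  excursions cancel, attenuating the confound.
* **Recruitment Monte-Carlo**: the residual confound under observed,
  Poisson-rate, discrete-uniform or point-mass recruitment distributions
  (`fit_poisson_rate()`, `run_recruitment_simulation()`,
  `compare_distributions()`).
* **A synthetic cohort generator** (`cohort_config()`, `generate_cohort()`)
  with multiplicative calendar-month seasonality, a linear aging trend,
  Poisson monthly counts and negative-binomial LOS, so the whole chain is
  testable without patient data, plus seasonal summary tables
  (`season_table()`) and between-season tests (`wilcoxon_rank_sum()`,
  `two_sample_t()`).

## Worked example

A synthetic 136-patient, three-zone cohort observed 2010–2012 under the
default study conditions:

```r
library(seasonsync)

coh <- generate_cohort(cohort_config(seed = 20))
w <- month_window(2010, 1, 36)

profiles <- lapply(setNames(nm = c("subtropical", "temperate", "colder")),
  function(z) {
    s <- monthly_series(coh$admissions, coh$patients, "los", w, zone = z)
    seasonal_profile(percent_deviation(s, fit_linear_trend(s)), zone = z)
  })
sapply(profiles, function(p) peak_deviation(p)$peak)
#> subtropical   temperate      colder
#>    56.26576   106.05929    44.85324

test <- subset(coh$patients, group == "test")
sync <- synchronized_profile(profiles,
  recruitment_schedule(test$zone, test$commencement_month, 12))
max_sync_deviation(sync)
#> $peak
#> [1] 6.013036   # residual confound after synchronization, in percent
```

The per-zone seasonal peaks are large (45–106% of baseline) because a
3-year window gives only three observations per calendar month; after
synchronizing to the 61 test patients' commencement dates the pooled
seasonal confound collapses to ~6%. Comparing recruitment distributions at
the same cohort:

```r
unif <- run_recruitment_simulation(profiles, 61, "uniform",
                                   list(window = 15), n_reps = 100, seed = 20)
pois <- run_recruitment_simulation(profiles, 61, "poisson",
                                   list(lambda = 6.5, window = 15),
                                   n_reps = 100, seed = 20)
unif
#> Recruitment simulation (uniform, n=61 patients, 100 reps): mean peak 9.94% (SD 3.23%)
pois
#> Recruitment simulation (poisson, n=61 patients, 100 reps): mean peak 10.76% (SD 3.00%)
```

Evenly spread recruitment leaves a smaller mean residual confound than
recruitment concentrated Poisson-fashion in mid-window; the contrast is
much sharper for single-zone profiles (see the vignette). The Poisson MLE
of a monthly recruitment-count series is its sample mean:

```r
fit_poisson_rate(rep(c(6, 7), 6))
#> [1] 6.5
```

`run_pipeline()` chains every stage (aggregate → trend → seasonal →
synchronize → simulate) from a YAML/list config and writes all artifacts as
CSV with a run log.

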