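---
title: "Seasonal variation in hospitalization outcomes and intervention-synchronized analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal variation in hospitalization outcomes and intervention-synchronized analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(seasonsync)
```

## The problem

Pre/post evaluations of home-telemonitoring programmes for chronically ill
patients compare hospitalization outcomes — admission counts and length of
stay (LOS) — before and after each patient's intervention begins. Both
outcomes carry strong calendar seasonality (winter–spring excesses in
temperate Australia, wet/dry contrasts in the subtropics). When patients are
recruited over many months, each patient's "post" period samples the
seasonal cycle at a different phase; ignoring this confounds the
intervention effect with season. `seasonsync` implements a three-stage
procedure for quantifying that confound and showing how synchronizing the
analysis to each patient's commencement date attenuates it:

1. **Baseline detrending.** For each climate subgroup, the outcome is summed
   over all patients within each calendar month of a multi-year
   pre-intervention window (36 months by default), and an ordinary
   least-squares line in the month index $t = 1,\dots,n$ is fitted. In an
   aging, chronically ill cohort both outcomes drift upward; the line is
   that secular "aging" baseline. `fit_linear_trend()` reports the slope,
   intercept, $R^2$, adjusted $R^2$, residual sum of squares, residual
   standard error, and the classical 95% prediction interval for a new
   monthly observation (t-quantile with $n-2$ df including the leverage
   term).

2. **Seasonal profile.** Each monthly value is replaced by its percentage
   deviation from the baseline,
   $d_t = 100\,(y_t - \hat y_t)/\hat y_t$, and the deviations at each
   calendar month are averaged across the years of the window
   (`percent_deviation()`, `seasonal_profile()`). The result is a 12-point
   profile $P(m)$ of mean percentage deviation per calendar month, with the
   across-years sample SD, per climate zone.

3. **Synchronized profile.** For test patients with commencement calendar
   months $c_k$ and zone profiles $P_{z(k)}$, the expected seasonal
   deviation experienced $i$ months after commencement is

   $$S_p(i) = \frac{\sum_{k:\ \text{monitored at } i} P_{z(k)}\big(((c_k + i - 2) \bmod 12) + 1\big)}{\#\{k:\ \text{monitored at } i\}},\qquad i = 1,\dots,12 .$$

   Patients whose follow-up is shorter than $i$ months drop out of the
   denominator (`synchronized_profile()`). Because commencement months are
   spread over the recruitment window, individual seasonal excursions enter
   $S_p$ at different phases and largely cancel; `max_sync_deviation()`
   reports the residual peak $\max_i |S_p(i)|$, the quantity of interest
   when arguing that a pooled, commencement-anchored analysis is seasonally
   unconfounded.

The recruitment Monte-Carlo (`run_recruitment_simulation()`,
`compare_distributions()`) asks how that residual peak depends on the
recruitment-date distribution: the observed list, independent
Poisson($\lambda$) month indices, a discrete uniform over the trial window,
or a same-month point mass. `fit_poisson_rate()` supplies the Poisson MLE
(the sample mean of monthly recruitment counts).

## Conventions and numerical choices

* **Calendar arithmetic.** Months are (year, month 1–12) pairs mapped to a
  linear integer index; all rotation is modular on 1–12, so a patient
  monitored past December wraps into the same yearly profile. No date
  library is involved beyond `Date` parsing at the CSV boundary.
* **Admission attribution.** An admission belongs wholly to the calendar
  month of its admission date, even when the stay spans months. This is the
  simplest convention consistent with summing outcomes "within each
  calendar month"; no LOS splitting is attempted.
* **Season maps.** Southern-hemisphere European seasons for temperate and
  colder zones (summer Dec–Feb, autumn Mar–May, winter Jun–Aug, spring
  Sep–Nov); a two-season wet ("summer", Nov–Apr) / dry ("winter", May–Oct)
  map for the subtropical zone.
* **Degenerate baselines.** Percentage deviation is undefined where the
  fitted baseline is at or below $\varepsilon = 10^{-9}\times$ the mean
  fitted value; such months raise an error naming the month rather than
  being dropped, since a near-zero denominator makes the percentage
  meaningless.
* **Peak ties.** The peaking month is the earliest calendar month attaining
  the maximum absolute mean deviation.
* **Dispersion at the peak.** The SD attached to a profile peak is the
  across-years SD at the peaking calendar month; the SD attached to a
  synchronized peak is the SD of the per-patient contributions at the
  peaking post-commencement month. Other sampling units are conceivable
  (across months, across patients within month), so peak SDs from other
  analyses of the same design are not directly comparable.
* **Poisson commencement mapping.** A raw Poisson draw $k$ becomes window
  month $k + 1$, clamped into $1..W$: zero draws commence in the first
  window month and draws beyond the window in its last. The generating
  MATLAB-style call this emulates can produce both, and no published
  convention exists, so this mapping is a declared choice of the package.
* **Inversion sampling.** Commencement draws are generated by inversion
  (one uniform per patient; `floor(Wu)+1` or the Poisson quantile
  function), so two simulations sharing a root seed consume identical
  uniform streams and replicate $r$ of each is drawn from the same state —
  the natural device for paired comparisons.
* **Exact rank-sum test.** `wilcoxon_rank_sum()` enumerates the null
  distribution of the rank sum over all assignments for combined $n \le
  20$, which remains exact under ties via midranks; the two-sided p is
  twice the smaller tail, capped at 1. Larger samples use the normal
  approximation with tie and continuity correction. The cut-over and the
  tie-exactness are the reasons this is implemented in the package rather
  than delegated; `stats::wilcox.test` serves as an independent cross-check
  in the test suite on tie-free and large-sample cases.
* **Between-season tests.** The sampling unit for seasonal comparisons is
  the monthly aggregate value within each season across years (9 values per
  four-zone season in a 3-year window; 18 per two-zone season). Published
  p-values from analyses whose sampling unit is unknown are not
  reproduction targets.

## The synthetic cohort generator

`generate_cohort()` draws, for each patient and window month $t$, a Poisson
admission count with mean
$\text{base\_rate} \times m_{z}(\text{cal.month}(t)) \times (1 +
\text{aging\_slope}\, t)$, where $m_z$ is the zone's 12-vector of positive
month multipliers. Seasonality is therefore **multiplicative** on the rate —
the paperless generative choice that makes percentage deviation from a
linear baseline the natural recovered quantity, with
$\mathbb{E}[\text{mean\_dev}(m)] \approx 100\,(m_z(m) - 1)$ when the
multipliers average 1. Each admission's LOS is $1 +$ negative binomial with
mean $\text{los\_mean} - 1$ and size `los_dispersion`, guaranteeing integer
stays of at least one day while allowing overdispersion.

Defaults emulate the observed study conditions: 136 patients split
subtropical 37 / temperate 31 / colder 68 with 21 / 17 / 23 in the test
group; a 36-month window starting January 2010; `base_rate` calibrated so
the expected total is about 817 admissions after accounting for the mean
aging factor ($817/(136\cdot36)/1.0925 \approx 0.153$ per patient-month);
`aging_slope` 0.005/month (a 20% rise over 3 years, consistent with a
visibly positive but noisy fitted slope); cosine month multipliers with
mean exactly 1, peaking in the austral winter (subtropical, amplitude
0.25), spring (temperate, 0.35) and autumn (colder, 0.05), sized to the
observed per-zone season contrasts (e.g. temperate spring/summer admission
ratio near 2); `los_mean` 6.3 days, anchored to the observed LOS-per-
admission regression slope of 6.31, with `los_dispersion` 1.2;
commencements uniform over the 15-month recruitment window that follows
the baseline years.

What the generator deliberately does **not** emulate: comorbidity mixes,
mortality and dropout, weather covariates, within-month admission
clustering, or year-to-year changes in the seasonal pattern itself. Passing
parameter-recovery tests on this generator therefore shows the estimation
chain is correct under a multiplicative stationary seasonal model — not
that real hospitalization series satisfy that model.

## Validation design

The test suite checks each stage against an independent oracle: OLS against
the closed-form normal equations; percentage deviation against element-wise
recomputation; the synchronized profile against a double-loop brute force
(exhaustively for all schedule sizes up to 10 patients); the exact rank-sum
p against explicit enumeration of all label assignments (combined $n \le
12$); peaks against exhaustive scans. Published summary arithmetic (season
shares such as 26.7% spring admissions, totals 817 admissions / 3627 LOS
days, LOS-per-admission 4.06–4.66 days) is reproduced by feeding the
published per-zone seasonal totals — expanded into synthetic per-admission
records — through the aggregation pipeline.

Stochastic properties use fixed-seed Monte Carlo at stated sizes: rate and
LOS recovery at $\ge 10^4$ patient-months/admissions within 3 standard
errors; null (flat-multiplier) profiles within Bonferroni-adjusted 3-sigma
bands per calendar month over 200 replicates of a 40-patient cohort;
multiplier recovery within 3 percentage points over 50 replicates of a
200-patient, base-rate-50 cohort; LOS slope recovery within 0.5 days at 500
patients. Synchronization attenuation is checked by the uniform-recruitment
limit: 1200 patients uniform over 12 months reduce a 100%-amplitude
sinusoidal profile to under 15% of its peak (20 seeds), while a same-month
schedule retains the full amplitude exactly.

For the recruitment-distribution ordering, the comparison unit is the
**mean** peak deviation over a simulation's replicates — the unit in which
such results are customarily reported — because the single-draw peak
distributions of uniform-over-15-months and Poisson(6.5) recruitment at 61
patients genuinely overlap (roughly 3–7% of independent pairs order the
wrong way). The acceptance check runs 100 paired repetitions of the two
simulations (25 replicates each, common root seed per pair) and requires
the uniform mean peak to be smaller in at least 95 of them; in practice the
means are separated by many standard errors and the ordering is essentially
deterministic, mirroring the published finding that evenly spread
recruitment roughly halves the residual confound relative to
Poisson-concentrated recruitment.

## Known limitations

* A linear baseline absorbs only a linear secular trend; if the true aging
  effect is convex over the window, residual curvature leaks into the
  seasonal profile. The 12-point profile is deliberately unsmoothed (no
  harmonic fitting).
* Seasonal profiles estimated from 3 years of data carry large
  uncertainties (3 observations per calendar month); the across-years SD
  honestly reflects this, and peak estimates are upward-biased by
  max-selection over 12 noisy means.
* The synchronized profile treats the zone profile as a fixed template;
  patient-level heterogeneity in seasonal response enters only through the
  per-patient contribution SD.
* `run_pipeline()` analyses one pre-intervention window; it does not
  adjust post-intervention outcome data, which is out of scope by design —
  the method estimates the residual confound rather than correcting
  outcomes.

## A worked run

```{r, eval = FALSE}
cfg <- list(
  generator = list(seed = 20),     # defaults: 136 patients, 3 zones, 2010-2012
  outcome = "los",
  simulation = list(dist = "poisson", params = list(lambda = 6.5, window = 15),
                    n_reps = 100),
  output_dir = "seasonsync-out",
  seed = 20
)
res <- run_pipeline(cfg)
res$fits$temperate
peak_deviation(res$profiles$temperate)
max_sync_deviation(res$sync)
res$sim
```
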