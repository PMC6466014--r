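# foodtweetenv

Geotagged social-media food mentions as census-tract food-environment
indicators, linked to chronic-disease prevalence.

`foodtweetenv` is for epidemiologists and health-geography researchers
who want to turn a stream of geotagged short-text posts into
neighborhood food-environment measures and relate them to small-area
health outcomes. It implements, as one tested R pipeline:

* **Text scoring** — a calorie-annotated food lexicon with healthy and
  fast-food classes; job-posting exclusion; greedy longest-leftmost
  multi-word matching on word boundaries; per-post caloric density
  (sum of matched terms' kcal/100 g) and class flags.
* **Tract assignment** — even-odd (ray-casting) point-in-polygon on
  GeoJSON census tracts, boundary-inclusive, deterministic tie-breaks,
  grid-accelerated with an exact brute-force reference path.
* **Aggregation** — per-tract mean caloric density and percent
  healthy / fast-food mentions; tracts with fewer than 10 food posts
  excluded; inner join with outcome and covariate tables;
  z-standardization on the analysis set.
* **Models** — for each outcome *y* (obesity, diabetes, hypertension
  prevalence, %) the adjusted median regression

  &nbsp;&nbsp;&nbsp;&nbsp;β̂ = argmin<sub>β</sub> Σ<sub>i</sub> ρ<sub>0.5</sub>(y<sub>i</sub> − x<sub>i</sub><sup>⊤</sup>β),&nbsp;&nbsp;ρ<sub>0.5</sub>(u) = |u|/2,

  with x containing the three standardized exposures plus 11
  demographic covariates; solved by smoothed IRLS finished by an exact
  basis-exchange step, bootstrap SEs (200 case-resampling replicates),
  and an independent simplex LP oracle (`lad_lp_oracle`) for
  verification. Plus OLS sensitivity fits, a Gaussian GEE
  (exchangeable working correlation, robust SEs) for state-level
  yearly calorie trends, and a Chow F test for group differences.
* **Synthetic data** — a seeded generator for tract grids, post
  streams, outcome and covariate tables with *planted* effects, so the
  entire analysis is testable without any external data.

## Worked example

Generate a small synthetic world and run the full pipeline:

```r
library(foodtweetenv)

dir <- tempfile()
cfg <- synth_config(seed = 7, n_states = 4, tracts_per_state = 25,
                    tweets_per_tract_mean = 70)
simulate_bundle(cfg, dir)      # tweets.jsonl, tracts.geojson, lexicon.csv, ...

res <- run_all(run_config(list(
  tweets     = file.path(dir, "tweets.jsonl"),
  tracts     = file.path(dir, "tracts.geojson"),
  lexicon    = file.path(dir, "lexicon.csv"),
  outcomes   = file.path(dir, "outcomes.csv"),
  covariates = file.path(dir, "covariates.csv"),
  state_map  = file.path(dir, "state_map.csv"),
  out_dir    = file.path(dir, "out"),
  boot = 200L, seed = 7L, outcome_list = "obesity")))
writeLines(make_report(res))
```

prints (abridged):

```
Outcome: obesity (median regression, n = 100)
  (Intercept)             28.1089 (SE 5.0587, p 2.751e-08) *
  z_mean_calories          0.2543 (SE 0.2039, p 0.2122)
  z_pct_healthy           -0.2623 (SE 0.2040, p 0.1985)
  z_pct_fastfood           0.2507 (SE 0.1816, p 0.1675)
  ...
State summary (post-weighted):
  01     n=   528  cal=  539.7  healthy= 29.5%  fastfood= 32.6%
  ...
Yearly calorie trend (GEE): +10.96 kcal/year (robust SE 5.070)
```

Reading it: each `z_` coefficient is the change in median obesity
prevalence (percentage points) per one standard deviation of that
tract exposure — here the generator planted +0.19 (calories), −0.30
(healthy) and +0.15 (fast food), and the 100-tract fit recovers them
within its bootstrap SEs (at this small size the SEs are ~0.2, hence
no stars; the acceptance study below uses 600 tracts × 20 replicates).
The trend line is the GEE estimate of the planted +15.87 kcal/year
calorie drift from a small noisy world. `res$manifest` carries the
stage counters (lines read = malformed + job-filtered + non-food +
food), seed and versions.

Per-stage functions (`load_lexicon`, `process_stream`,
`assign_tracts`, `aggregate_tracts`, `filter_min_tweets`,
`merge_outcomes`, `standardize`, `state_summary`,
`fit_median_regression`, `fit_ols`, `fit_gee_trend`, `chow_test`) are
exported individually; `inst/cli/foodtweet-env.R` is a thin Rscript
front end (`simulate`, `process`, `run`, `trend`).

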