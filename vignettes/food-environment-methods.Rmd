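---
title: "Methods: social-media food mentions as neighborhood food-environment indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: social-media food mentions as neighborhood food-environment indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Traditional food-environment indicators (distance to supermarkets,
fast-food outlet density) are expensive to survey and say little about
what residents actually eat and talk about eating.  Geotagged
short-text posts offer a running, passively collected signal: posts
that mention food can be scored for caloric density and classified as
mentioning healthy foods or fast-food restaurants, then aggregated to
census tracts.  `foodtweetenv` implements that pipeline end to end and
the statistical models used to relate the tract indicators to
tract-level chronic-disease prevalence (obesity, diabetes,
hypertension), together with a synthetic-data generator that makes
every stage testable offline.

The three tract exposures are

* **mean caloric density**: mean over a tract's food posts of the sum
  of matched terms' kcal per 100 g,
* **percent healthy mentions**: share of food posts matching at least
  one healthy term (fruits, vegetables, nuts, lean protein),
* **percent fast-food mentions**: share matching at least one
  fast-food term,

all z-standardized over the analysis set, so a coefficient reads as
the change in outcome prevalence (percentage points) per one standard
deviation of the exposure.

## Text scoring

Posts and lexicon terms share one normal form: lowercase, `#`/`@`
stripped (so `#pizza` matches), punctuation removed at token edges,
whitespace collapsed.  Job postings are removed *before* food matching
(a job advert that mentions pizza is not a food post); the exclusion
phrase list is configurable because no canonical list exists.

Matching is greedy longest-leftmost over the token sequence: at each
position the longest lexicon term starting there wins and the scan
advances past it.  Word boundaries are respected (`pineapple` never
matches `apple`) and each distinct term counts once per post — the
per-post caloric density is a presence-weighted sum, not an occurrence
count, because a repeated mention is more plausibly emphasis than a
second serving.  The test suite checks the matcher against a
brute-force oracle that enumerates every boundary-respecting candidate
and resolves overlaps longest-first.  The two strategies coincide
unless one lexicon term overlaps the *interior* of a longer term that
starts later (e.g. `big mac` vs a hypothetical `mac and cheese`); the
bundled lexicon avoids such chains, and users supplying their own
lexicons should too if they care about this edge.

The bundled ~60-term lexicon is an explicitly synthetic stand-in with
plausible kcal/100 g values: the full nutrient-database-derived
keyword list is not redistributable here, and nothing in the pipeline
depends on the stand-in beyond its CSV schema.

## Tract assignment

Points are assigned to tract polygons with the even-odd (ray-casting)
rule in planar lon/lat.  Census tracts are a few kilometres across, so
Earth curvature is negligible at the decision boundary.  Three
determinism choices matter only on measure-zero sets but make runs
reproducible: boundary points count as inside; when several tracts
contain a point (shared edges), the lexicographically smallest tract
id wins; multi-part tracts contain a point if any part does, holes
counted even-odd within a part.  A uniform grid over tract bounding
boxes prefilters candidates; the brute-force all-pairs path is kept
callable (`method = "brute"`) and the two are required to agree
exactly in the acceptance suite.

## Aggregation choices

* **Minimum-post filter**: tracts with fewer than 10 *food* posts are
  dropped; a tract with exactly 10 is kept.  The filter counts food
  posts rather than all posts because the food-post count is the
  denominator of every tract indicator — it is the quantity whose
  stability the filter protects.
* **Standardization happens after the outcome merge**, on the analysis
  set, so "per one SD" refers to variation within the modeled sample,
  which is how the coefficients are interpreted.
* **State summaries are post-weighted** by default (total flagged food
  posts over total food posts), matching the "percent of food posts"
  reading; unweighted tract means are available via
  `weighting = "tract"`.

## Median regression

The primary model estimates the conditional *median* prevalence:
\[
\hat\beta = \arg\min_\beta \sum_i \rho_{0.5}(y_i - x_i^\top\beta),
\qquad \rho_{0.5}(u) = |u|/2 ,
\]
robust to the heavy right tail of tract prevalence distributions.
The solver is iteratively reweighted least squares with weights
$1/\max(|r_i|,\varepsilon)$, $\varepsilon = 10^{-6}$, at most 200
iterations, convergence when the largest coefficient change drops
below $10^{-8}$.  Pure Lawson-type reweighting zigzags once $p$
residuals pin near zero, so at the median the IRLS estimate is
finished by an exact basis-exchange step: a least-absolute-deviation
optimum interpolates $p$ observations, and a candidate basis $A$ is
optimal iff $g$ solving $X_A^\top g = \sum_{i\notin A} w_i\,
\mathrm{sign}(r_i)\, x_i$ satisfies $|g_j| \le w_j$.  The exchange
walks to the first residual sign-crossing otherwise.  This certificate
makes the reported `converged` flag an optimality statement, not a
step-size heuristic.  If ties (more zero residuals than parameters)
defeat the certificate, small problems fall back to an exact simplex
solve of the equivalent linear program.

That linear program — minimize $\sum_i (u_i^+ + u_i^-)$ subject to
$y - X\beta = u^+ - u^-$ — is also implemented independently as a
full-tableau primal simplex with Bland's rule (`lad_lp_oracle`) and
serves as the oracle: on random instances the production path must
match its optimum to $10^{-4}$ relative check loss (it matches to
machine precision in practice).

**Standard errors** are nonparametric case-resampling bootstrap
(default 200 replicates, seeded), with p-values from the normal
approximation.  The published analysis does not state its SE method;
the bootstrap is assumption-light and honest about the two-stage
nature of the exposures.  Resampling is implemented as multinomial
case *weights* on the original rows, which is equivalent to row
resampling but keeps the design in general position for the exact
polish.  Replicates that fail to converge would be dropped and
counted (`boot_used` in the diagnostics); in practice none are.

An OLS fit with classical SEs (`fit_ols`) is the sensitivity
companion, and `chow_test` compares group-specific fits (e.g. male-
vs female-specific obesity surfaces) through the pooled-vs-separate
residual-sum-of-squares F statistic.

## GEE temporal trend

Yearly trends in state-level mean calories per food post are estimated
with a Gaussian identity-link marginal model: outcome = state-year
mean, regressor = calendar year centered at 2015, clusters = states,
exchangeable working correlation (the conventional default for
repeated state measures; independence is available and, on balanced
data, leaves the point estimate unchanged), robust sandwich standard
errors.  The exchangeable correlation estimate is clamped to
$[-0.99, 0.99]$ so the working covariance stays invertible when
residuals are cluster-constant (e.g. noise-free synthetic data); the
clamp does not move point estimates on balanced designs.

## The synthetic world

The generator states one desk-scale world and the tests live in it:

| knob | default | emulates |
|---|---|---|
| states x tracts | 10 x 60 | a contiguous-US-like tract panel |
| posts per tract | Poisson(80) | three years of geotagged collection |
| food fraction | 0.35 | share of posts mentioning food |
| job fraction | 0.05 | job adverts that name foods |
| healthy/fast-food propensity | Beta(2, 10) per tract | per-*term* class rates (mean ~0.17); with 1–3 terms per post, per-*post* mention shares land near 25–35% |
| outcome noise SD | 1.0 percentage point | unexplained prevalence variation |
| planted z-scale effects | published effect sizes | ground truth for recovery |
| calorie drift | +15.87 kcal/year | secular trend in food mentions |

Food posts embed 1–3 lexicon terms in filler text; the term class
follows the tract's latent propensities, and the within-class term
choice is exponentially tilted by year so that the *expected* calories
per food post rise by the configured drift (the tilt rate is solved by
root finding each year).  Outcome prevalences are built on the
*measured* tract z-scores — prevalence = baseline + planted effects +
covariate effects + noise — so a correctly specified regression
recovers the planted values without attenuation from finite post
counts, and exactly (to $10^{-6}$) when the noise is switched off.
Eleven demographic covariates are drawn independently with plausible
marginals; their contributions enter through internally standardized
values so the planted exposure effects stay on the stated scale.

What a green recovery test establishes: the pipeline's measurement,
filtering, standardization and estimation steps compose correctly and
without systematic bias at realistic effect sizes.  What it does not
establish: anything about real posting behavior — no bots, no
user-level correlation, no spatial autocorrelation, no lexical
ambiguity beyond the bundled lexicon, and outcomes generated from the
very indicators the pipeline measures rather than from an independent
health process.

## Numerical and degenerate-input policy

* Standardization refuses constant columns by name; it needs at least
  two tracts.
* Rank-deficient designs fail naming the collinear columns; missing
  rows are dropped complete-case with a logged count.
* The Chow F is floored at 0 against floating-point noise; it errors
  when $n_A + n_B \le 2k$.
* Degenerate rings (< 4 vertices with closure) and unclosed rings are
  rejected at load; malformed post lines are counted, never fatal.
* All generators are deterministic under a fixed seed, to the byte,
  and every stochastic fit takes an explicit seed.

## Known limitations

Median regression at quantiles other than 0.5 is exposed but the
exact polish only runs at the median; other quantiles rely on plain
IRLS.  The GEE implementation covers the one model shape the pipeline
needs (intercept + year).  Geometry is planar; do not use the
assignment step poleward of ~70 degrees latitude.  The acceptance
recovery studies compare replicate-mean estimates against planted
values; they are calibration checks, not re-analyses of the original
data.
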