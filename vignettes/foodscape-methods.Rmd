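---
title: "Mobile food environments and fast-food visits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mobile food environments and fast-food visits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`foodscape` studies a question from nutritional epidemiology: how much of
the decision to eat fast food is driven by the food environment a person
is exposed to right before the meal, as opposed to stable individual
preference? Because the population-scale mobility data this question
demands is proprietary, the package pairs every analytic tool with a
synthetic-city generator that reproduces the statistical structure the
analysis relies on, so the whole pipeline is testable end to end.

## The environment metric

The food environment around a planar location $x$ is summarised by
$\phi(x)$, the ratio of fast-food outlets (FFO) to all food outlets (FO)
near $x$. Two definitions are provided:

* **radius**: FFO/FO among outlets within 1 km of $x$ (Euclidean,
  outlets at exactly the radius included). Undefined (`NA`) when no FO is
  in range.
* **k-NN**: the FFO share among the 25 nearest FO, which adjusts for
  outlet density. Distance ties break by ascending `poi_id` so results
  are reproducible.

Per user $i$, three exposure summaries follow: $\phi^h_i$ at the home
location; the mobile exposure
$\phi^m_i = \sum_t \tau_{it}\,\phi(x_{it}) / \sum_t \tau_{it}$, a
stay-duration-weighted average over *all* stays (stays with an undefined
environment are dropped with their weight); and
$\mu_i$, the fraction of the user's food-outlet visits that are fast
food.

## The visit-decision model

Conditional on a lunch food outing, the probability that user $i$ picks a
fast-food outlet on day $t$ is modelled as

$$\Pr(y_{it}=1) = \mathrm{logit}^{-1}\!\left[\beta_0 + \alpha_i + \delta_t
  + \beta\,\phi(c_{it})\right],$$

where $c_{it}$ is the **context**: the last place the user occupied
before 11:30 on that day. User effects $\alpha_i$ absorb stable
preference; day effects $\delta_t$ absorb city-wide daily variation; the
slope $\beta$ is the quantity of interest. A context only enters the
analysis when its environment contains both outlet types — otherwise no
real choice existed — and users who never, or always, chose fast food at
lunch are excluded (they carry no within-user information).

Estimation is Newton/IRLS maximum likelihood on a sparse indicator
design (`Matrix`), with step-halving so the likelihood trace is monotone,
convergence at max-absolute-score $< 10^{-8}$, and a 100-iteration cap.
Users and days whose outcomes separate are dropped before fitting,
iterated to a fixed point. Identifiability is resolved by reporting
sum-to-zero user and day effects with the grand mean folded into
$\beta_0$; predictions are invariant to this choice. The slope's standard
error is two-way cluster-robust (user and day) by inclusion–exclusion —
cluster-by-user plus cluster-by-day minus cluster-by-cell — with a
$G/(G-1)$ factor per component; the rare non-positive-definite case falls
back to the larger one-way component with a warning.

One refinement is applied by default to the reported slope. The
dummy-variable MLE of a fixed-effects logistic model is inconsistent for
fixed panel length: with $T_i$ decisions per user the slope carries
incidental-parameter bias of order $1/T_i$, and the both-outcomes
inclusion filter (an outcome-based truncation) adds to it. At the
package's study conditions (about 33 decisions per user) this bias is
roughly $+0.08$ on a true slope of 1.87 — small in relative terms but
visible against the sampling spread. `fit_fe_logit()` therefore reports a
split-panel-jackknife-corrected slope: the panel is split into odd and
even days, the bias delta is estimated as the mean half-panel slope minus
the full-panel slope *on the users fittable in all three fits* (half
panels lose far more users to the inclusion filter, and letting the
population drift would overstate the correction), and subtracted from the
full-panel MLE. The uncorrected `beta_mle` is always retained, and
`bias_correction = "none"` switches the correction off. Standard errors
are the full-panel clustered ones in both modes.

The interpretation helper `odds_change(beta, dphi)` returns
$(e^{\beta\,\Delta\phi}-1)\times 100$: with $\beta = 1.87$, a 10-point
increase in the context's fast-food share raises the odds of a fast-food
visit by about 20% (20.56%).

### The DMV variant

Visits to DMV offices approximate random assignment of people to an
unfamiliar food environment. Users typically appear there once, so
$\alpha_i$ is not estimable; the user's observed fast-food fraction
$\mu_i$ stands in for preference and day effects are dropped. Whether
$\mu_i$ should carry a free slope or enter as a unit-slope offset is
genuinely ambiguous; both are implemented, the free slope is the default
(statistically safer — it nests the offset), and results are reported with
the mode named. Errors are clustered by user via `sandwich::vcovCL`.

## Why the generator looks the way it does

The generator's defaults define the study conditions; they were fixed at
design time and are not tuned per analysis.

* **City**: a 20 km square tiled by a 10×10 grid of area units; 2000
  POIs placed as a clustered point process (five commercial hotspots over
  a uniform background). 40% of POIs are food outlets; the expected
  fast-food share among them is 0.15, so that area-level $\phi$ straddles
  the 0.13 Low/High boundary used downstream. Fast-food flags follow a
  *rough* spatial propensity field (bump width one-eighth of the extent):
  food swamps must exist at the kilometre scale for errand-day contexts
  to vary. Demographics follow a smoother income field with independent
  noise per covariate, so the demographic OLS is well conditioned.
  Non-food categories are drawn from planted per-area profiles
  (mall/office/residential/airport-like), which is what makes topic
  recovery testable.
* **Users**: homes uniform; habitual morning anchors at non-food POIs
  biased toward commercial areas (people decide about lunch near work
  and shopping, not at home); preferences $\alpha_i \sim N(0, 1)$. The
  1.0 scale matches the wide spread of observed per-user fast-food
  fractions (an IQR of roughly 0.03–0.27 implies a logit spread of about
  two).
* **Mobility**: every user-day is home → anchor (spanning the 11:30
  cutoff) → optional afternoon excursion → home, with a 5-minute minimum
  stay. On half the days (`errand_prob = 0.5`) the last pre-lunch stay is
  a morning errand at a POI within 3 km of the anchor. This is the single
  most important design choice in the package: with a fixed anchor,
  $\phi(c_{it})$ would be constant within user and $\beta$ would be
  *unidentified* once $\alpha_i$ is in the model. Errand days supply the
  within-user contrast that identifies the slope, exactly as day-to-day
  context variation does in real mobility data.
* **Outings**: whether a lunch outing happens at all is exogenous
  (Bernoulli, `outing_prob = 0.6`); the model only describes the
  FFO-vs-non-FFO choice conditional on an outing. The rate was chosen at
  design time by a bias analysis: the unconditional fixed-effects
  logistic MLE carries incidental-parameter bias of order $1/T_i$ in the
  per-user decision count, and 60-day panels need roughly 30+ decisions
  per user to keep the slope bias acceptably small. 0.6 gives
  $T_i \approx 33$ while remaining a plausible weekday lunch-outing rate.
* **Changers**: 0.46% of users relocate their morning anchor on a
  mid-study day (uniform on the central 60% of the panel so both windows
  exist), assigned round-robin to Low→High, High→Low, Low→Low, High→High
  strata (Low < 0.10, High > 0.20 at the anchor). Changers are planted
  only at anchors whose environment contains both outlet types —
  otherwise their context days would be removed by the choice filter and
  the natural experiment would start censored.
* **DMV**: a handful of offices placed uniformly; 5% of users get
  exactly one visit at a uniformly chosen office, independent of home
  location — the quasi-random-assignment argument in generative form.

What the generator deliberately does *not* emulate: realistic trip
chaining or exploration/return dynamics, road networks, opening hours,
multi-city heterogeneity, and geographic coordinates (the city is planar,
in meters, so the 1 km radius is exact). A further honest divergence from
real data: with only one anchor neighbourhood per user, home and mobile
exposure are more strongly correlated here than in observed mobility,
so passing tests demonstrate the machinery recovers what the generative
model encodes — not that real cities look like this.

## Context extraction conventions

One convention set, applied everywhere and tested at the boundaries:
the context stay must *start* strictly before 11:30 (it may span the
cutoff); the lunch window is the half-open $[11{:}30, 14{:}00)$;
post-stay windows ("within two hours") are $(\text{end},
\text{end}+120]$, closed on the right; when several food visits fall in
one window the earliest defines the outcome. Full-day contexts keep one
row per stay with a missing outcome when no food visit follows, because
the intervention machinery needs the context even when no decision
happened — only rows with decisions enter sums over decisions.

## The natural experiment

Per user, the daily mean context series is screened by binary
segmentation with a weighted CUSUM statistic; the best split is accepted
only if a 999-permutation test rejects homogeneity at $\alpha = 0.01$,
with at least 10 observed days on each side. This changepoint design is a
stand-in: the original analysis names only the model family. Detected
movers are classified at the $\phi = 0.13$ threshold (a mean of exactly
0.13 counts as Low — the published strict inequalities leave the boundary
undefined, and a deterministic rule was needed).

Group series pool visits by event time (days since each user's change
day): the pooled fraction is fast-food visits over all food visits, i.e.
a visit-count-weighted mean of per-user fractions; unweighted per-user
averaging is available as an option. Pooling is the default because the
published series are visit-level fractions.

The counterfactual for the Low→High movers is built from the Low→Low
movers (people who also changed *place*, but not environment — using
non-movers would confound moving itself), via a local-level structural
time-series model with the control series as a regression covariate:
$y_t = \mu_t + \gamma x_t + \varepsilon_t$, $\mu_{t+1} = \mu_t + \eta_t$.
Parameters are estimated by maximum likelihood with a Kalman filter on
the pre-change period (diffuse initial level); post-change predictions
come from 1000 posterior-predictive draws at the MLE, so intervals widen
with horizon as the random-walk level diffuses. The cumulative effect is
anchored at zero on the change day. Pre-periods shorter than 20 observed
days fall back to a difference-in-means counterfactual with a constant
interval, flagged in the result. Plug-in (MLE) predictive draws slightly
understate parameter uncertainty; the calibration suite checks that null
coverage of the 95% cumulative interval stays in the 90–99% band.

## Interventions

A unit intervention in area $\Omega$ shifts the local ratio by
$\delta\phi/\delta I = -1/n_\Omega$ (one fewer fast-food outlet among the
area's $n_\Omega$ food outlets; any other derivative can be supplied).
Under the fitted full-day model the predicted change in fast-food visits
is

$$\Delta^{\mathrm{FFO}}(\Omega) = \sum_{c_{it}\in\Omega}
  \beta\,p_{it}(1-p_{it})\,\frac{\delta\phi}{\delta I},$$

summed over decision contexts located in the area (point-in-cell, edge
ties to the lowest `area_id`). Contexts of users absent from the fit are
excluded and the coverage is logged; days unseen by the fit use the
constrained mean $\delta = 0$. Four selection strategies are ranked at a
fixed budget: largest area-level $\phi$ (food swamp), largest $\phi$
among flagged low-food-access areas, most decisions (food hotspots), and
largest $|\Delta^{\mathrm{FFO}}|$ (behaviour–environment). Because the
score is additive over contexts, top-$k$ selection is exactly optimal for
the behaviour–environment strategy, which therefore dominates the others
by construction — the interesting quantity is *how much*, and for whom:
averted decisions are decomposed by the decider's income quintile and by
the obesity-prevalence tertile of their home area. The averted fraction
uses the model-predicted baseline ($\sum p_{it}$ over all decision
contexts) as denominator, consistent with the numerator's model basis.

Area profiles come from latent Dirichlet allocation on the
area-by-category POI count matrix (20 topics by default, symmetric
Dirichlet priors $1/K$, collapsed Gibbs with 500 sweeps and an internal
deterministic RNG so a seed fully reproduces the fit). Topic enrichment
of a selection is the mean topic weight in selected areas over the mean
weight everywhere.

## Numerical choices and degenerate inputs

* Environment queries deduplicate repeated locations and are chunked;
  they equal the brute-force all-pairs computation exactly (tested).
* A city with no fast food (or only fast food) forces the corresponding
  degenerate outcome in the generator rather than sampling an outlet that
  does not exist.
* `fit_fe_logit` refuses constant-$\phi$ designs (slope unidentified),
  panels with fewer than two users or days after filtering, and
  non-convergence (with iteration diagnostics).
* The demographic OLS z-standardises predictors, rejects collinear pairs
  by name and rank-deficient designs, and reports $\pm 1.96\,\mathrm{SE}$
  intervals.
* Changepoint detection needs at least `2 * min_segment` observed days,
  returns `NA` (with a warning) otherwise, and treats a zero-variance
  series as changeless without running permutations.

## Problem sizes used by the validation suite

The packaged tests exercise the full pipeline at the scale the package
targets: slope recovery uses 100 independent cities of 2000 users × 60
days; counterfactual calibration uses 100 injected-shift and 200 null
series; changepoint calibration uses 100 shifted and 500 null series of
180 days; fixtures (`make_fixture()`) provide sub-second scenarios for
everything else. These sizes are the package's statement of the
conditions under which its guarantees were verified.

## Known limitations

The generator's mobility is schematic (one anchor, one errand, no trip
chains), outings are exogenous rather than chosen, and $\phi$ is computed
from a static outlet catalogue. The fixed-effects MLE carries
incidental-parameter bias of order $1/T_i$; at the packaged study
conditions this is small relative to the sampling spread but it is a
property of the estimator users should know about at shorter panels. The
counterfactual's intervals are plug-in rather than fully Bayesian. None
of the published real-data magnitudes should be read off synthetic runs;
the synthetic city validates the *method*, qualitatively mirroring the
real analysis' directions.
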