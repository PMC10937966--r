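# foodscape

Poor diets are a leading driver of chronic disease, and one long-standing
hypothesis is that *food environments* — the mix of outlets around the
places people actually spend their days — nudge food choices. Most
research has looked only at the static environment around home and found
mixed results. `foodscape` implements the complementary, mobility-centric
analysis: it measures the fast-food environment people are exposed to as
they move (not just where they sleep), models the decision to visit a
fast-food outlet as a function of the environment at the *pre-meal
context*, exploits habitual-context changes and DMV errands as natural
experiments, and ranks food-environment interventions by their predicted
behavioural impact.

Because the population-scale mobility data such studies use is
proprietary, the package ships a synthetic-city generator that reproduces
the statistical structure the analysis needs (clustered venues, food
swamps, anchored daily routines, context changers, quasi-random DMV
errands), so every stage is verifiable end to end. It is aimed at
quantitative epidemiologists and urban-data scientists who want to study,
teach, or extend this class of analysis.

## The model

The food environment at a location $x$ is $\phi(x)$, the ratio of
fast-food outlets (FFO) to all food outlets (FO) within 1 km (or among
the 25 nearest FO). Per user, $\phi^h_i$ is the home environment,
$\phi^m_i = \sum_t \tau_{it}\phi(x_{it})/\sum_t \tau_{it}$ the
stay-duration-weighted mobile exposure, and $\mu_i$ the observed
fast-food share of food visits. Conditional on a lunch outing, the visit
decision follows a fixed-effects logistic model

$$\Pr(y_{it}=1) \;=\; \mathrm{logit}^{-1}\!\big[\beta_0 + \alpha_i +
\delta_t + \beta\,\phi(c_{it})\big],$$

where $c_{it}$ is the last place user $i$ occupied before 11:30 on day
$t$. The slope is estimated by sparse Newton/IRLS maximum likelihood with
two-way (user, day) cluster-robust errors and a split-panel jackknife
correction for incidental-parameter bias. `odds_change(beta, 0.1)`
translates it into the percent change in visit odds for a 10-point richer
fast-food context; at $\beta = 1.87$ that is $+20.6\%$, i.e. roughly 20%.

An intervention that shifts an area's ratio by
$\delta\phi/\delta I=-1/n_\Omega$ changes predicted fast-food visits by
$\Delta^{\rm FFO}(\Omega)=\sum_{c_{it}\in\Omega}\beta\,
p_{it}(1-p_{it})\,\delta\phi/\delta I$; four targeting strategies (food
swamps, low food access, food hotspots, behaviour–environment) are
compared on this scale, with LDA topic profiles describing the kinds of
places each strategy selects.

## Worked example

```r
library(foodscape)

cfg <- sim_config(seed = 42, n_users = 300, n_days = 40, n_areas = 36,
                  city_extent_m = 12000, n_pois = 900, n_hotspots = 4,
                  dmv_count = 0L)
run <- run_end_to_end(cfg, budget = 4, n_topics = 6)
print(run)
#> <foodscape_run>
#>   300 users, 53962 stays, 7150 food visits
#>   median phi_mobile 0.097, median phi_home 0.060, median mu 0.130
#>   rho(phi_m, mu) = -0.001 vs rho(phi_h, mu) = -0.045
#>   beta_hat = 2.254 (SE 0.494): +10pp fast food in context -> +25.3% odds
#>   strategy totals (delta FFO visits):
#>     food_swamp             -10.5612
#>     low_food_access        -2.1763
#>     food_hotspots          -21.4356
#>     behavior_environment   -25.8843
```

Reading the output: the synthetic population's median mobile exposure is
9.7% fast food versus 6.0% around home, and a median 13% of food visits
are to fast food. The fitted slope (generative truth 1.87; at 300 users
the estimate 2.25 ± 0.49 brackets it) says a 10-point richer pre-lunch
context raises the odds of choosing fast food by ~25% in this small run.
The strategy totals are predicted fast-food visits averted by converting
one fast-food outlet per selected area: targeting by predicted behaviour
change (`behavior_environment`) beats targeting high-ratio areas
(`food_swamp`) more than two-fold here, because high-$\phi$ areas are not
where influenceable decisions happen — the same qualitative conclusion the
mobility literature draws. At the packaged study scale (2000 users, 60
days; see the methods vignette) the slope estimate concentrates tightly
around the generative value.

Individual stages are ordinary functions on tibbles
(`generate_city()`, `simulate_mobility()`, `extract_lunch_contexts()`,
`fit_fe_logit()`, `detect_transitions()`, `estimate_counterfactual()`,
`score_areas()`, `evaluate_strategies()`, `fit_poi_topics()`), with
`tidy()`/`glance()` methods and `autoplot()`s for the fitted objects.

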