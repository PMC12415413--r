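# xylemix

Partitioning tree root water uptake (RWU) among soil depths and individual
precipitation events from continuous in-situ stable-isotope time series.

## The problem

Continuous membrane-probe systems measure the stable isotope composition of
water (δ²H, δ¹⁸O, ‰ vs VSMOW) in tree xylem and in soil at several depths at
a daily rhythm, alongside heat-pulse sap-flow sensors, soil moisture probes
and precipitation sampling. From these series an ecohydrologist wants to
know, day by day: *which* soil depths and *which* precipitation events the
tree is drinking from, how *old* that water is, and how fast the water from
a single rain event moves through the tree.

`xylemix` implements that inference chain as composable, tested R functions:

1. **Calibration** — drift correction against repeated in-house standards and
   the liquid–gas affine correction (`drift_correct()`,
   `fit_linear_correction()`, `calibrate_series()`).
2. **Alignment** — daily gridding with conservative linear gap-filling
   (`align_daily()`; interior gaps ≤ 7 days only, never extrapolated).
3. **Sap flow** — heat-pulse processing with the heat-ratio (HRM) and Tmax
   dual method, `v = (k/x)·ln(ΔT_d/ΔT_u)` below the crossover velocity and
   `v = √(x² − 4kt_max)/t_max` above it, zero-flow night correction, and
   scaling to stand transpiration (`compute_sapflow()`).
4. **Bayesian mixing model** — for each day the xylem signature `x` is a
   convex mixture of source signatures: `x ~ N(Σⱼ pⱼμⱼ, ξ·Σⱼ pⱼ²σⱼ² + τ²)`
   per tracer, with `p ~ Dirichlet(α·w)`. The prior weight `w` carries the
   root-density profile (depth mode) or amount/recency weighting
   `amount / days elapsed` (event mode). Sampled by an adaptive
   Metropolis-within-Gibbs sampler in C++ (`fit_mixture()`,
   `mixture_series()`), cross-checkable against a deterministic simplex
   grid posterior (`mixture_grid_posterior()`).
5. **Derived quantities** — contribution-weighted mean RWU depth
   (`mean_rwu_depth()`), sap-flow-weighted absolute uptake in litres per day
   (`absolute_uptake()`), water-age distributions and cumulative age curves
   (`age_distribution()`), event transit times under the ≥ 10 % contribution
   rule (`transit_time()`), the asymptotic uptake kinetics
   `y(t) = a − (a − b)e^(−ct)` (`fit_uptake_curve()`), and rule-based
   segmentation of a season into wet / dry-down / dry / recovery / final-wet
   periods (`segment_periods()`).
6. **Synthetic campaigns** — a generator with full ground truth
   (`simulate_campaign()`): seasonal precipitation isotopes on a local
   meteoric water line, a lagged per-layer soil mixing cascade with topsoil
   evaporative enrichment, a moisture-driven RWU rule, VPD-driven sap flow
   emitted as invertible heat-pulse records, and two deuterium labelling
   pulses (+1017.08 ‰ at 7 mm, +801.15 ‰ at 23 mm).

Everything takes and returns tibbles, chains with the pipe, and has
`tidy()` / `glance()` / `autoplot()` methods for the fitted objects.

## Worked example

```r
library(xylemix)
library(dplyr)

camp <- simulate_campaign(scenario_config(), seed = 1)

# depth-resolved mixing over the season
xylem <- align_daily(camp$xylem_obs, aggregate = "none")
soil  <- align_daily(camp$soil_obs)
set.seed(1)
series <- mixture_series(xylem, build_depth_sources(soil),
                         pool_trees = TRUE,
                         mcmc = mix_mcmc(chains = 4, iter = 2000, warmup = 1000))

series |>
  mutate(depth = as.numeric(sub("depth_", "", source_id))) |>
  mean_rwu_depth() |>
  summarise(season_mean = mean(mean_depth_m))
#> # A tibble: 1 × 1
#>   season_mean
#>         <dbl>
#> 1       0.281
```

The posterior-mean uptake depth tracks the campaign's drought signal: about
0.25 m on average while the topsoil is wet, deepening to about 0.40 m during
the dry phase as the upper layers empty. A single day's fit prints its
posterior summary with split-chain R-hat and effective sample size per
source:

```r
day1 <- as.Date("2022-06-01")
set.seed(2)
fit <- fit_mixture(filter(xylem, date == day1),
                   filter(build_depth_sources(soil), day == day1))
tidy(fit)
#> # A tibble: 4 × 8
#>   source_id  prior_weight    mean      sd       q2.5  q97.5  rhat   ess
#>   <chr>             <dbl>   <dbl>   <dbl>      <dbl>  <dbl> <dbl> <dbl>
#> 1 depth_0.05        0.277 0.288   0.0879  0.0932     0.418   1.01 239.
#> 2 depth_0.20        0.297 0.237   0.160   0.0137     0.605   1.01 239.
#> 3 depth_0.40        0.416 0.473   0.0770  0.296      0.588   1.01 273.
#> 4 depth_0.90        0.01  0.00248 0.00397 0.00000134 0.0140  1.39  37.0
```

`mean` is the posterior fraction of xylem water drawn from each depth that
day; the 0.40 m layer dominates and the 0.90 m layer contributes almost
nothing while water is plentiful (its near-empty posterior mixes slowly,
which the R-hat column reports honestly).

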