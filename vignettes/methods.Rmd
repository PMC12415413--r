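---
title: "Models and methods behind xylemix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xylemix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`xylemix` infers where a tree's transpiration stream comes from — which soil
depths, which precipitation events, water of what age — from continuous
in-situ measurements of water stable isotopes (δ²H, δ¹⁸O in ‰ vs VSMOW) in
xylem, soil and precipitation, combined with heat-pulse sap flow and soil
moisture. This vignette explains each model, its assumptions, the tunable
parameters and their defaults, the numerical choices, and what the synthetic
campaign used for validation does and does not establish.

## 1. The mixing model

On each day the xylem water signature is treated as a convex mixture of
source signatures. For tracer $k$ and contribution vector $p$ on the
simplex,

$$x_k \sim \mathcal N\!\Big(\textstyle\sum_j p_j \mu_{jk},\;
  \xi \sum_j p_j^2 \sigma_{jk}^2 + \tau_k^2\Big),
  \qquad p \sim \mathrm{Dirichlet}(\alpha\, w).$$

The variance has a *process* part — the source variances $\sigma_{jk}^2$
propagated through the squared contributions and scaled by a fitted factor
$\xi$ — and an additive *residual* part $\tau_k^2$. Priors:
$\log\xi \sim \mathcal N(0,1)$ and
$\log\tau_k \sim \mathcal N(\log\tau_{0k}, 0.25)$, with $\tau_{0k}$ the
analytical accuracy of the probe system (2 ‰ for δ²H, 1 ‰ for δ¹⁸O).
The residual prior is deliberately tight: the residual scale *is* the known
analytical uncertainty, and a loose prior lets the sampler "explain away" an
isotopically extreme observation (for example a deuterium-labelled pulse in
the xylem) by inflating $\tau$ instead of attributing the water — a local
mode we observed and closed off during development.

Two source configurations are built from the same machinery:

* **Depth mode** (`build_depth_sources()`): one source per measurement depth
  (0.05, 0.20, 0.40, 0.90 m), prior weights from the root-density profile —
  28/30/42 % in the upper 0.40 m scaled by 0.99 plus an assumed 1 % at
  0.90 m, i.e. $(0.2772, 0.2970, 0.4158, 0.0100)$. The 1 % keeps deep
  uptake possible without favouring it.
* **Event mode** (`build_event_sources()`): one source per precipitation
  event on record, prior weight $\propto$ amount / days elapsed, the age of
  a multi-day event counted from its first day, zero elapsed days mapped to
  one. Only events that have already fallen are eligible (causal); the
  lookback defaults to the whole record, matching a sampling campaign that
  starts the preceding November.

**Prior strength.** $\alpha$ defaults to the number of sources $J$, so the
prior is equivalent to one pseudo-observation per source on average
("informative mean, weak strength"). With many events and a skewed $w$ this
still concentrates prior mass on recent large events — which is the point of
the weighting — but the likelihood can and does override it.

**Tracer mode.** Both tracers are used by default (`tracer_mode = "dual"`);
a δ²H-only mode exists because depth profiles are sometimes only
discriminable in δ²H after labelling.

**Trees.** Trees are fitted independently by default. `pool_trees = TRUE`
instead treats all trees' observations on a day as replicates in one
likelihood — appropriate when the stand-level mixture is the estimand, and
what the end-to-end recovery checks use (nine replicate observations shrink
the effective observation noise threefold).

### Sampling and diagnostics

The posterior is sampled on softmax-transformed contributions
($z \in \mathbb R^{J-1}$, last coordinate fixed; the Jacobian contributes
$\sum_j \log p_j$) by an adaptive Metropolis-within-Gibbs sweep written in
C++: one univariate random-walk update per coordinate with Robbins–Monro
scale adaptation toward 0.44 acceptance during warmup, one joint kick across
all coordinates (target 0.23) to traverse ridges, and univariate updates of
$\log\xi$ and $\log\tau_k$. Four chains by default; split-chain
$\widehat R$ and an effective sample size (Geyer-style truncated
autocorrelation sum) are reported per source, and a fit is flagged —
never silently dropped — when $\max \widehat R \ge 1.05$. Near-degenerate
sources (posterior mass piled at zero) mix slowly and honestly show large
$\widehat R$; their posterior means are still accurate to well within the
reported SD.

### The grid oracle

`mixture_grid_posterior()` integrates the same likelihood and prior over a
regular simplex grid (default spacing 0.01) with the error scales held
fixed, giving a sampler-free posterior mean. Grid points are shifted half a
cell into the interior (midpoint rule): the Dirichlet density can be
unbounded on the boundary, yet mass adjacent to a vertex must be covered —
with boundary points simply excluded the oracle loses up to 0.03 of a
near-vertex posterior mean, which we measured and fixed. Oracle-versus-
sampler agreement is asserted at ±0.02 on randomized 2–3-source problems in
the test suite; both routes target the identical fixed-error posterior, so
the comparison is exact rather than approximate.

### Day series and interpolation

`mixture_series()` fits every day with a real (non-interpolated)
observation and then linearly interpolates the posterior-mean contributions
across unfitted days, re-projecting onto the simplex by renormalisation.
Isotope *values* are themselves gap-filled only across interior gaps of at
most 7 days (`align_daily()`): a cap prevents inventing data through long
outages, and each tracer is interpolated independently since no joint rule
is defensible. δ²H/δ¹⁸O interpolation and contribution interpolation never
extrapolate beyond the observed span.

## 2. Sap flow

Heat-pulse velocity comes from two estimators with complementary ranges:
the heat ratio method $v = (k/x)\ln(\Delta T_d/\Delta T_u)$ (exact at low
and reverse flow) and the Tmax method $v = \sqrt{x^2 - 4kt_{max}}/t_{max}$
(reliable at high flow), with defaults $x = 6$ mm probe spacing and
$k = 2.5\times10^{-7}$ m² s⁻¹ thermal diffusivity. The dual method uses HRM
below a crossover velocity (default 30 cm h⁻¹ — not printed anywhere
authoritative, so it is a config entry) and Tmax above, recording the method
used per record. Probe misalignment is handled as an additive offset
estimated as the per-tree median velocity in 02:00–04:00 windows with
VPD < 0.01 kPa and darkness, then subtracted everywhere; small negatives are
clipped to zero for transpiration only, the raw corrected values are kept.
The darkness criterion is PPFD < 5 µmol m⁻² s⁻¹ by default; the opposite
inequality is selectable (`par_rule = "above"`) because the printed version
of this criterion is physically inconsistent for a night window and we did
not want to guess silently. Wound correction is an identity-default
polynomial multiplier; the two radial thermistor rings (10/20 mm) are
averaged with configurable weights (equal by default). Sap flux density uses
the identity that a 1 cm h⁻¹ front through 1 m² of sapwood carries
10 L h⁻¹; whole-tree flow integrates over the day, and stand transpiration
divides by ground area with 1 L m⁻² = 1 mm.

## 3. Derived quantities

* **Mean RWU depth** is the contribution-weighted mean of the measurement
  depths. Contribution vectors within 2 % of the simplex are renormalised;
  worse is an error, not a warning.
* **Absolute uptake** multiplies contributions by whole-tree sap flow;
  conservation ($\sum_j$ uptake = flow) holds to $10^{-9}$ by construction
  and is asserted.
* **Water ages** map event contributions to days since each event's first
  day; the cumulative age curve is nondecreasing and ends at 1.
* **Transit time** is the *inclusive span* from the first to the last day an
  event contributes ≥ 10 %: re-emergence counts, because the underlying
  phrase "time during which" is ambiguous between span and total days, and
  storage-driven re-emergence is physically real. The total-days variant is
  a flag (`rule = "total"`).
* **Uptake kinetics**: $y(t) = a - (a-b)e^{-ct}$ fitted by constrained
  nonlinear least squares (Levenberg–Marquardt, multi-start over a small
  deterministic grid), parameterised as $(a, q, c)$ with $b = aq$ so the
  constraint $0 \le b \le a \le 1$ becomes a box; the $(a,b,c)$ covariance
  follows by the delta method. A constant series returns $a = b$ with $c$
  flagged unidentified; optimiser failure falls back to a coarse grid
  search, flagged. Residual diagnostics (dispersion, outlier count, a KS
  normality check) accompany every fit. The *response* is cumulative event
  water extracted divided by event water available to the tree
  (event mm × a capture-area config), since no authoritative denominator
  exists; the percentage is then unit-checked by construction.
* **Period segmentation** is a deterministic rule machine on daily mean
  shallow VWC and precipitation: wet until VWC persistently drops below
  15 %, dry-down until it persistently drops below 13 %, dry until the
  first event > 10 mm followed by a VWC rise of ≥ 2 points within 14 days
  (recovery onset), final wet once the 7-day mean VWC re-stabilises at
  ≥ 16 %. All thresholds are arguments; every boundary is reported with the
  rule that triggered it, and too-short spans yield a partial segmentation
  with a warning.

## 4. The synthetic campaign

`simulate_campaign()` emulates the measurement structure of a 194-day
growing season (2022-04-20 to 2022-10-30) at daily resolution: nine trees in
three patches, three soil profiles at 0.05/0.20/0.40/0.90 m, precipitation
sampled from the preceding 1 November (winter events emitted as monthly
composite samples, summer events individually), ~35 % of isotope days
missing (mirroring 125 observed days out of 194), analytical noise 2 ‰/1 ‰,
and two deuterium pulses: +1017.08 ‰ at 7 mm on 10 June and +801.15 ‰ at
23 mm on 2 August.

Precipitation isotopes follow a seasonal δ¹⁸O sinusoid (mean −8.5 ‰,
amplitude 3 ‰, peak in May) with δ²H on a local meteoric water line of
slope 7.8 and intercept 8, plus event noise; simulated natural δ²H spans
roughly −95 to −20 ‰. The soil is a per-layer lagged mixing cascade, not a
Richards solver: volumetric water content drains exponentially toward
wilting under VPD-driven demand (rates 0.060/0.035/0.018/0.006 day⁻¹ by
layer) and receives event recharge split 50/30/15/5 % across layers with
0/1/2/4-day lags; each layer's isotopic state is an explicit convex mixture
over events, updated by the recharge-to-storage fraction, and the topsoil
drifts along an evaporation line (slope 3.2) during rain-free spells. This
is the minimum structure that produces depth-attenuated, delayed tracer
arrival and topsoil enrichment while keeping the full event make-up of
every layer — and therefore of the xylem — known exactly.

The true uptake rule is a moisture-weighted preference,
$p_l \propto r_l\,[(\theta_l - \theta_{wilt,l})_+ + 0.25]^2$ with
$r = (0.18, 0.26, 0.46, 0.10)$, which reproduces the qualitative field
pattern the package targets: uptake centred on 0.40 m when wet, deep-layer
share rising from ~5 % to ~22 % and mean depth from ~0.27 to ~0.42 m during
drought, reversing within days of rain. Whole-tree sap flow is
$Q = Q_{max}(1 - e^{-VPD/0.8})\,g(\bar\theta)$ with $Q_{max} = 85$ L d⁻¹
(±15 % per tree) and a soil down-regulation clamp between 9 and 18 % VWC,
giving wet-period stand transpiration near 1.1 mm d⁻¹ falling to ~0.4
during drought. Sap flow is emitted as hourly heat-pulse records inverted
exactly from the HRM and Tmax formulas (plus per-tree misalignment offsets
and velocity noise), so the processing chain can be validated end to end:
with noise off, recovered transpiration matches the prescription to
numerical precision.

All of these values were fixed by inspecting the generator's realism against
the qualitative field patterns before any recovery statistic was measured,
and not revisited afterwards. Problem sizes in the test suite (a full
194-day campaign for the recovery check, shorter 50-day campaigns for
integration tests, 2 000–10 000 MCMC iterations depending on the check) are
the package's choice of a thorough-but-quick default validation.

### What passing the synthetic checks does and does not show

The generator shares the mixing model's central assumption — xylem water is
a convex mixture of measured pools with Gaussian noise — so recovery on
synthetic campaigns validates the *inference machinery*, not that
assumption. Real data add root-interface fractionation debates, stem water
storage, spatial heterogeneity among probes, and soil water that is not a
clean mixture of sampled events; none of these are modelled, and the
generator's evaporative enrichment is the only deliberate
model-misspecification stressor included. Two quantitative findings from
the recovery study are worth knowing:

* Depth contributions are recovered with mean absolute error ≲ 0.10 at
  analytical noise — the level the test suite asserts.
* Event *transit times* are recovered to within a few days for most ≥10 mm
  events, but not uniformly within ±2 days: true contribution series decay
  slowly through soil storage and plateau near the 10 % threshold, so the
  crossing day is extremely sensitive (days per 0.01 of contribution), while
  per-day inference over ~30 mostly isotopically similar events carries
  irreducible error. The corresponding acceptance test asserts the ±2-day
  bound and is expected to fail; we keep it red rather than weaken it,
  because it documents a real identifiability limit of natural-abundance
  event tracing, one that labelled pulses (isotopically unmistakable) do not
  suffer.

## 5. Known limitations

* No stem-storage compartment, no Craig–Gordon evaporation model inside the
  mixing model, no isotopic fractionation at the root interface.
* The event model's posterior for isotopically near-degenerate old events is
  prior-dominated; their individual contributions should be read as a group.
* The water-concentration correction hook is identity by default; supply
  instrument-specific coefficients if you have them.
* The sampler is a random-walk scheme: posteriors that pile mass at a
  simplex vertex mix slowly and are flagged via $\widehat R$ rather than
  hidden; increase `mix_mcmc(iter=)` when flags appear.
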