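---
title: "Modelling cycling uptake: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cycling uptake: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycleimpacts)
```

This vignette is the package's own account of its model: what is
assumed, which parameters matter, what the synthetic data do and do not
emulate, and where design choices were genuinely open.

## The model

The unit of analysis is a one-week travel diary: a persons table (age,
gender, ethnicity, socioeconomic class, car access, region, survey
weight) and a trips table (main mode, distance in miles, duration in
minutes, diary day, purpose), optionally with mode-specific stages.
Internal units are fixed — miles, minutes, mph — with converters
(`miles_from_km()`) at the boundary.

Two diary conventions are applied before any modelling:

- **Short-walk replication.** Diaries of this design record walks under
  1 mile only on the final diary day; each such walk is replicated six
  additional times so a week's walking is not undercounted. Replicates
  are real trip rows carrying a `replicate_of` marker rather than a
  weight, which keeps all trip-level outcome code uniform; the marker
  also makes the operation idempotent.
- **Public-transport walking.** For bus/rail trips, walking minutes are
  summed from the trip's walking stages into `pt_walk_minutes`, making
  the active part of motorised trips visible to the activity accounting.

A *current cyclist* is a person with at least one cycle (or e-bike)
trip in the diary week.

### Step 1: becoming a regular cyclist

Given a target share *t* of the population who are regular cyclists and
a baseline prevalence *b*, exactly `round((t − b) × N)` non-cyclists
convert, drawn without replacement from those aged under 80. Quota
sampling (rather than independent Bernoulli conversion) was chosen
because the scenario's defining quantity is the population share of
regular cyclists: the quota makes it exact and the draw deterministic
given the seed. Under *equity* the draw is uniform; otherwise each
person's sampling weight is their age-band × gender stratum's baseline
cyclist prevalence, so with the observed national prevalences (8.4%
males 18–59, 3.7% females 18–59, 4.4% males 60–79, 1.6% females 60–79)
a younger male non-cyclist is roughly twice as likely to convert as an
older one. Prevalence and quota use unweighted person counts; the
synthetic surveys carry unit weights, and diary weights enter all
outcome computations instead.

Two boundary rules follow from restricting uptake to ages 18–79. The
5% target is only defined where baseline prevalence is below 4%
(elsewhere it is refused). And at the 100% level the arithmetic quota
exceeds the eligible pool whenever any non-cyclist is 80 or older, so
the 100% scenario is defined as *everyone eligible converts* — the
quota is capped at the under-80 pool.

### Step 2: switching trips

For every trip of every converted person, the probability of switching
to cycling is the propensity of the person's age-band × gender stratum
in the trip's distance band. Propensity is estimated from current
cyclists as a survey-weighted ratio of sums: cycled trips over all
trips, per stratum × band. Default bands (miles) are [0,1), [1,2),
[2,3), [3,5), [5,8), [8,12), [12,∞): resolution where cycling is
plausible, an open tail beyond. Cells supported by fewer than 30 trips
(configurable) fall back to the band's pooled all-strata estimate —
with ratio-of-sums estimators the pooled value is identically the
support-weighted average of the stratum values, so pooling never
shifts the band's overall level. Bands with no cyclist trips at all
get propensity 0 with a warning.

Cycling speeds are stratum-level ratios of sums (total cycled miles /
total cycled hours), falling back to the pooled speed and then to a
configurable default (8 mph). E-bike speed (default 9.5 mph) comes
from the reference configuration, constant across strata.

Under e-bike scenarios all new cyclists are assumed to have e-bike
access: the cycled-or-not decision uses the e-bike owners' per-band
propensity (a flatter distance decay), and cycled trips are assigned
e-bike vs traditional bike by the band's choice probability, both flat
across age and gender. Trips beyond the last reference band carry the
last band's values. The bundled `ebike_reference()` values — except
the 53% share of e-bike owners who also own a traditional bike — are
illustrative placeholders; estimate them from an e-bike-recording
survey with `build_ebike_tables()` when one is available.

Switched trips keep their trip id and distance; the mode becomes
cycle/e-bike, the duration is recomputed as `distance / speed × 60`,
and embedded public-transport walking is zeroed — the whole
door-to-door trip becomes cycling, so re-adding its access walk would
double-count activity. Existing cyclists' non-cycled trips are *not*
re-switched: Step 2 applies only to converted persons. After Step 2
the adult population partitions exactly into existing cyclists,
new cyclists (converted, ≥ 1 switched trip), regular cyclists
(converted, none switched — possible because bands with low propensity
may switch nothing) and non-cyclists.

### Scenario enumeration

Six target levels × equity on/off × e-bike on/off give 24 raw
combinations per geography. Where baseline prevalence is ≥ 4% the four
5% combinations are dropped. At the 100% level the equity switch no
longer changes who converts; one duplicate — (100%, equity on, e-bike
off) — is removed, giving 23 specifications for a low-baseline
geography and 19 otherwise, hence 6×19 + 4×23 = 206 across England and
its nine regions with four low-baseline regions. A full equity
collapse at 100% would arguably remove a second duplicate (the e-bike
variant), but the per-geography counts 23/19 are the established
convention for this enumeration and we keep it; the 100%-level specs
that remain differ only in their e-bike flag once equity is moot.

### Physical activity

Weekly travel activity is marginal MET-hours: intensity × hours summed
over walk trips (2.6 MMET), cycle trips (4.6), e-bike trips (3.5) and
the embedded walking minutes of public-transport trips (2.6). Marginal
METs count only energy above rest, which is why a one-hour cycle
contributes 4.6 rather than the absolute 5.6 MET-hours.

Non-travel activity comes from a separate cross-sectional sample and
is fused by within-stratum rank matching: persons ranked by travel
MMETh (seeded random tie-breaks) receive the matching weighted
quantile of their stratum's non-travel distribution. This preserves
the shape of both marginals, induces a transparent monotone coupling,
and is deterministic given the seed. It is a deliberate stand-in for a
richer statistical-matching procedure; the assignment is computed once
at baseline and reused bit-identically in every scenario, since
non-travel activity is assumed unchanged by cycling uptake.

Guideline attainment uses thresholds constructed from recommended
hours at the moderate-intensity midpoint of 3.5 MMET: 2.5 h × 3.5 =
8.75 MMETh/week and 5 h × 3.5 = 17.5 MMETh/week, with closed lower
bounds ("at least").

### Health

The comparative risk assessment maps each person's total MMETh to an
all-cause-mortality relative risk via a configurable lookup curve with
linear interpolation between knots and a flat tail; the first knot is
pinned at (0, 1) and the curve must be monotone non-increasing in
(0, 1]. The bundled `default_dose_response()` has the steep-then-
plateau shape reported by pooled cohort meta-analyses (plateau ≈ 0.66)
but is explicitly illustrative — substitute the published curve of
your choice via CSV. A lookup table subsumes any published functional
form while keeping the interpolation contract testable.

Within each geography × age-band × gender cell (ages 20–79; persons
18–19 and 80+ are excluded from burden attribution though not from
travel outcomes), the population impact fraction is

    PIF = 1 − Σᵢ wᵢ · rr(scenarioᵢ) / Σᵢ wᵢ · rr(baselineᵢ)

computed on individual exposures — this matters because the curve is
nonlinear, so a person's *starting point* determines the benefit of an
extra MMETh. Absolute burden averted is PIF × stratum YLL (deaths
identically); aggregate percentages are burden-weighted. Impacts are
against a hypothetical constant state: no time dimension, lags or
life-table dynamics.

### Transport and emissions

Car vehicle-miles count car-driver trips only; passenger trips enter
mode share but would double-count vehicles in miles (a configurable
convention via `include_passenger`). CO₂e is exactly car miles ×
0.313 kg per mile, so relative changes in CO₂ equal relative changes
in car miles by construction. Public-transport reductions deliberately
earn no CO₂ credit: fewer passengers need not shrink the bus or rail
fleet's mileage. Journey-time deltas compare the recomputed cycling
duration against the previously self-reported duration (for public
transport including waiting); exact ties count as neither faster nor
slower.

## The synthetic data generator

`generate_population()` emulates the statistical structure the model
consumes, not any particular survey's microdata:

- demographics drawn from configurable age × gender × ethnicity ×
  region shares; ages uniform within band;
- current-cyclist flags per stratum prevalence (defaults 8.4/3.7/4.4/
  1.6%, overall ≈ 4.8–4.9%; regional multipliers default to baselines
  between 3.1% in the North East and 6.1% in the South West, four
  regions below 4% so the 5%-level exclusion rule is exercisable);
- Poisson trip counts (mean 14/week ≈ two trips a day), per-mode
  lognormal distances, durations from mode speeds with lognormal
  noise (sdlog 0.15);
- cycle trips carved out of flagged cyclists' trips by a logistic
  distance-decay rule `plogis(1.0 − 1.3·log d)`, scaled so the overall
  cycle mode share matches the configured share in expectation. This
  gives the propensity estimator real structure to recover (cyclists
  cycle a decaying subset of their trips) and makes configurations in
  which the cycle share exceeds what flagged cyclists could supply
  detectably infeasible.

Trip counts, distance distributions and the non-travel activity gamma
parameters are placeholders chosen to be realistic in magnitude — no
public source prints them — and are clearly configurable. The
generator does not reproduce household clustering, seasonality,
day-of-week structure, purpose–mode dependence, income gradients, or
any spatial detail (routes, hilliness). Consequently, passing tests
demonstrate the *mechanics and internal consistency* of the engine —
conservation, calibration recovery, closed-form health arithmetic —
not empirical accuracy for any real population. Headline magnitudes
from desk-scale synthetic runs (e.g. ≈ 2% car-mile reduction in the
25% exemplar) happen to be plausible but should not be quoted as
estimates for England.

Activity samples are gamma per stratum; burden tables are rate ×
population / 1e5 with illustrative all-cause YLL and death rates
rising steeply with age. All generators are pure functions of their
configuration and seed.

## Numerical conventions

- Exact quota: `round()` on the increment; ties in weighted sampling
  handled by base R's sequential weighted draw without replacement.
- Seeds: every stochastic operation evaluates under a locally-set seed
  and restores the caller's RNG state. Scenario child seeds are
  `(global_seed + hash(geography|target|equity|ebike)) mod (2³¹ − 1)`,
  so results do not depend on enumeration order.
- Rank-matching tie-breaks use a seeded uniform draw as a secondary
  sort key, never perturbed arithmetic.
- Stage-duration validation allows a 5-minute tolerance above the trip
  duration (independently rounded self-reports).
- Propensity/speed estimation: minimum cell support 30 trips with
  pooled fallback; empty bands 0 with warning; speeds fall back pooled
  → default. Degenerate inputs (no cyclists, no e-bike trips, missing
  strata in the activity sample) raise classed errors naming the
  offending unit.
- Validation rejects a load outright with row-level diagnostics (ids
  listed) rather than silently dropping rows.

## Problem sizes

The test suite exercises the engine at 2,000–20,000 synthetic persons
(50,000 for prevalence-recovery checks, 200 seeds for sampling-ratio
checks), and the acceptance script runs the full pipeline at 50,000
persons; these sizes give the binomial checks 3-standard-error
resolution while keeping a full run in seconds on one CPU.

## Known limitations

Beyond the synthetic-data caveats above: no injury, air-pollution or
noise pathways; no morbidity or life-table outcomes; no uncertainty
propagation (single deterministic run per seed); no suppressed or
induced demand (trip sets and distances are fixed); no congestion or
speed feedback; mode-switch probability depends on distance band and
age/gender stratum only, by design — richer behavioural covariates
would be setting-specific and harder to interpret. The e-bike
reference and dose-response defaults are illustrative and should be
replaced with published tables for applied work.
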