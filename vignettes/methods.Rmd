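---
title: "Temporally explicit habitat suitability: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporally explicit habitat suitability: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riparianSDM)
```

## The problem

Riparian vertebrates in Mediterranean-climate regions experience stream
habitat through its *regime*: almost all precipitation arrives in a few
winter storms, hydrographs rise and recede within days, many reaches dry
out every summer, and consecutive wet or dry years reshape conditions on
the 3–10-year timescale over which populations establish or disappear.
A species-distribution model built on long-term average flow therefore
asks the wrong question. The pipeline in this package asks instead: what
were the flow and temperature conditions *in the years leading up to each
observation*, and how do occurrence probabilities shift when those
conditions are projected to the end of the century?

## Windowed hydrologic metrics

All metrics are computed on windows of whole water years (1 October –
30 September, labelled by the ending calendar year) terminating with the
water year that contains the observation date. "3-years prior" is
ambiguous between calendar and water years; whole water years were chosen
so each window holds an integer number of complete wet-dry cycles, which
keeps seasonal metrics comparable across windows. Horizons a record
cannot cover are reported as missing, never as zero.

The registry covers the metric families that matter in flashy
intermittent systems:

| metric | definition | units |
|---|---|---|
| `rbi` | Richards–Baker flashiness, Σ\|ΔQ\|/ΣQ | – |
| `recession_rate` | median of ln Q_{t−1} − ln Q_t over days with strictly decreasing positive flow | 1/day |
| `hydroperiod` | fraction of days with Q above a threshold (default 0) | – |
| `storm_count`, `days_since_storm` | maximal runs above a storm threshold; runs separated by a single sub-threshold day merge | count, days |
| `drought_count`, `drought_dur_max` | maximal no-flow (Q ≤ 0) spells and the longest one | count, days |
| `q10`, `q50`, `q90` | daily-flow percentiles, linear interpolation between order statistics | m³/s |
| `wet_season_mean`, `dry_season_mean` | mean flow Nov–Apr / May–Oct | m³/s |

Numerical conventions are pinned so every metric admits an exact
brute-force oracle: quantiles interpolate linearly (the convention under
which the median of 1…100 is 50.5), the recession estimator returns
−ln r exactly for a geometric recession with ratio r, and RBI is
invariant to rescaling discharge. The storm threshold defaults to 9× the
window median daily flow — an effective-discharge convention — and is
configurable, as is the drought threshold (default: no flow). On an
all-zero window RBI is undefined and returned as missing with a warning
rather than silently zero.

## Synthetic data: what it emulates and what it does not

The generator suite produces every input with known ground truth, which
is what makes the downstream stages testable.

- **Watersheds**: elevations up to the regional ceiling of 2646 m, forced
  to span both sides of the 375 m high/low-elevation split; areas
  lognormal around ~20 km²; riparian cover and baseflow index uniform on
  their percentage ranges.
- **Precipitation**: storm days arrive with probability 0.25 in
  November–April and 0.015 in May–October with gamma depths, so ≥85% of
  annual totals fall in the wet season. Interannual wet/dry variation
  enters as a lognormal per-year multiplier (σ_log = 0.5, mean 1), and an
  orographic factor rises with elevation. Totals are exactly linear in
  the multiplier, which gives a closed-form scaling test.
- **Streamflow**: a single linear reservoir per reach — storage gains
  P·area, loses a seasonal evapotranspiration drain (floored at empty),
  and discharges a fraction k per day. The default k = 0.25 produces the
  flashy hydrographs and summer no-flow spells typical of small
  Mediterranean watersheds; a unit pulse recedes geometrically with ratio
  1 − k, giving exact oracles for the recession estimator, and with the
  drain off the system is linear and mass-conserving. This is a
  deliberately minimal runoff model: it has no snow, no sub-daily
  dynamics, no hydraulic routing, and one storage per reach.
- **Temperature**: weekly air temperature follows a seasonal cosine with
  an elevation lapse and a linear warming trend expressed in °C per
  century (centred on 1998, so two periods with midpoints Δ years apart
  differ by warming·Δ/100 in expectation — 3.72 °C between the 1982–2014
  and 2082–2100 means under 4 °C/century). Weekly stream temperatures are
  exact linear functions of air temperature and the four watershed
  attributes plus Gaussian noise, so the regression stage has a planted
  truth it must recover exactly at zero noise.
- **Traits**: cluster prototypes are constructed to differ on every
  trait, species join prototypes round-robin, and each trait is corrupted
  to another level with probability `flip_prob`; true labels are returned
  for scoring recovery.
- **Occurrences**: Bernoulli draws with
  p = 1/(1 + exp(−(a + b·metric))) against any metric at any horizon —
  including 3-year windows, so the claim that short-window antecedent
  conditions carry signal is itself testable. Draws sample reach/date
  combinations without replacement while the pool lasts, keeping records
  unique at the deduplication grain.

Because storms, reservoirs and responses are all idealized, passing tests
demonstrate that the *machinery* recovers planted structure — not that
real survey data are this clean. Real data add detection error, spatial
autocorrelation, non-random survey placement and hydrologic model error,
none of which the generator emulates.

## Occurrence preparation

Records collapse to one per (species, reach, year, month). Within a merge
group any presence dominates: detection is imperfect, so an absence is
weaker evidence than a presence. Records whose reach lacks even 3-year
flow coverage at the observation date are dropped with a logged count
rather than imputed. Because windows align to water years, all
observation dates within a water year share flow features, and the model
table can equivalently be built from a precomputed metric table.

## The two species distribution models

**Streamflow.** Each metric × horizon feature is screened with a
one-predictor logistic regression; features with Wald P ≤ α (default
0.05; relax to 0.2 for data-poor species) enter a 500-tree random forest.
No multiple-testing correction is applied at the screen — deliberately,
since the screen only gates entry to a forest that tolerates redundant
predictors, and correcting would trade false inclusions (cheap) for
false exclusions (costly). Occurrence probability is the fraction of
trees voting "present" — an exact multiple of 1/500, with a 250/250 tie
reported as 0.5 rather than forced to a class. Performance is reported
as hold-out accuracy on a stratified 25% validation split plus the
out-of-bag error on the training 75%. The split is stratified by class
and seeded; forest hyperparameters beyond the tree count stay at the
library defaults (√p candidate features per split, unlimited depth).

**Stream temperature.** The six annual metrics (max-of-weekly-max,
mean-of-max, min-of-weekly-min, mean-of-min, mean-of-mean, and annual
range) are near-collinear by construction, so they are standardized,
reduced to two principal components, and a logistic regression is fit on
the scores. Standardization and rotation default to the supplied scaling
table — use the pooled baseline + end-of-century metrics to mirror a
projection workflow that scales future metrics on the same axes; note
this leaks the future distribution into the scaling, so a baseline-only
scaling table can be passed instead. A reach-year needs ≥40 of 52 weeks
to yield metrics; thinner years are missing, not extrapolated. Predicted
weekly triples are clamped to max ≥ mean ≥ min with a logged count.

## Projection

Future metrics are averaged across GCMs *first*, then fed to the SDM
once — the ensemble mean is computed as the first member plus the mean of
member differences, which makes averaging an exact no-op when members
agree and order-invariant always. Change is end-of-century minus
baseline per reach, summarized by the regional mean and 5th/95th
percentiles; elevation strata split at 375 m (inclusive on the high
side) and are compared with a Welch t-test by default (rank-sum
optional) — with very small strata the test is skipped and the p-value
reported missing. The temperature track is annual (per-year fields, a
least-squares trend of the annual mean), while the flow track is
per year-type (wet/dry/moderate), mirroring the asymmetric treatment of
the two drivers. The limiting variable for a reach is simply the driver
with the lower probability; exact ties are called "neither".

## Problem sizes and test design

The test suite and acceptance script run on a 40-reach, 33-water-year
synthetic study — enough reaches to stratify by elevation and enough
years that 3-, 5- and 10-year windows differ materially, while a full
run stays in the minutes range on a laptop. Planted SDM studies use 800
records and an effect of 8 log-odds units per SD of the driver (Bayes
accuracy ≈ 0.95), a "strong but not deterministic" response. Statistical
properties are asserted as rates over seeds (e.g. cluster recovery in
≥95/100 seeds, screening retention inside the binomial band around α
over 1,000 null datasets) rather than single draws.

## Known limitations

- The linear reservoir cannot produce hysteresis, snowmelt timing or
  overbank dynamics; regionalization skill on synthetic attributes says
  nothing about transferability of real regional regressions.
- The recession rate is constant across reaches under the generator
  (every falling limb of a linear reservoir has ratio 1 − k), so it
  carries no planted signal — a property of the stand-in hydrology, not
  of the estimator.
- No detection/occupancy modelling, no spatial autocorrelation
  correction, no dispersal constraints: projected fields assume any
  reach that becomes suitable is reachable.
- The dendrogram cut maximizes the merge-height gap; with clusters of
  very unequal tightness a silhouette-style criterion can disagree, and
  expert post-hoc regrouping is supported only as an external label
  override.
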