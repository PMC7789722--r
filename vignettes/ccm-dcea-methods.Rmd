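---
title: "Methods: a distributional CEA of community-based pneumonia treatment scale-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a distributional CEA of community-based pneumonia treatment scale-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmdcea)
```

## The problem

Community-based case management of childhood pneumonia (CCM) — diagnosis and
oral antibiotics delivered by community health workers — is one of the
cheapest ways to avert under-five deaths in high-burden settings, but its
coverage is uneven. In Ethiopia in 2016, the fraction of symptomatic children
who received treatment ranged from roughly a quarter to 59% across the eleven
major regions, while under-five mortality ranged from 39 to 125 per 1000
live births. A ministry planning to scale coverage up to the 90% universal
target faces a genuine policy trade-off: spend first where a treated episode
is cheapest (dense, urban regions), or first where children are worst off
(remote, high-mortality regions)?

`ccmdcea` implements the quantitative machinery to compare those options: a
deterministic Markov cohort model per region, incremental
cost-effectiveness ratios (ICERs), under-five deaths averted, and weighted
Gini coefficients summarizing how each strategy redistributes life
expectancy — a distributional cost-effectiveness analysis (DCEA).

## The cohort model

Each region's 2016 birth cohort is followed in annual cycles from birth
until extinction (120 cycles; nobody reaches age 120). Two arms are run:
*baseline*, at the observed 2016 treatment coverage, and *target*, at 90%
coverage. In each cycle a fraction `q(a)` of those alive dies; survivors are
credited one completed life year. The model is an expectation (cohort
proportions), not a microsimulation — there is no Monte Carlo error
anywhere in the pipeline.

The intervention operates only in the first five cycles (ages 0–4, the
under-five window CCM serves). During those ages the annual death
probability at coverage `c` is

```
q(a; c) = q_other(a) + incidence * CFR * (1 - efficacy * c)
```

with `CFR = 0.0351` the case fatality rate of an untreated episode,
`efficacy = 0.70` the proportional CFR reduction under treatment, and
`incidence` the region's episodes per child-year (derived from survey
point prevalence as `prevalence * 365 / duration`, with a 4.6-day mean
episode duration).

Two modelling conventions deserve emphasis:

* **Background mortality is all-cause at baseline coverage.** The survey
  mortality inputs already include pneumonia deaths at the observed
  coverage, so the baseline pneumonia component
  `incidence * CFR * (1 - efficacy * baseline_coverage)` is subtracted to
  get `q_other`, and scaling coverage to `c` changes mortality by exactly
  `incidence * CFR * efficacy * (c - baseline)` per intervention year. The
  alternative (treating survey mortality as pneumonia-free background and
  adding pneumonia on top) roughly doubles baseline under-five mortality
  and is rejected. For a few high-incidence regions the pneumonia
  component exceeds the reported child (age 1–4) all-cause probability;
  `q_other` is then clamped to zero with a warning. This is an input
  inconsistency we surface rather than hide: it leaves the *incremental*
  effects untouched (both arms share the clamped component) but inflates
  those regions' modelled baseline under-five mortality, which is why the
  modelled national baseline U5MR sits above the survey headline value
  while deaths averted and life-expectancy gains match the published
  analysis.
* **Expected episodes, not competing risks.** Treatment costs and deaths
  use `incidence` as an expected episode count per child-year with no
  within-year competing-risk correction; the products involved
  (`incidence * CFR` < 0.02) make the linear approximation smaller than
  the precision any of the published figures are reported at.

Life expectancy is the sum of the survival curve over cycles plus a flat
half-cycle correction of 0.5 years (deaths happen mid-cycle on average; the
correction is undiscounted). Effects are also reported discounted at 3%
per year, as `sum S(a) * 1.03^(-a)`. Treatment costs accrue at cycle start
among those alive — `S(a) * incidence * coverage * unit_cost * 1.03^(-a)`
over ages 0–4 — which matches published cost totals to well within their
rounding. Because a cohort member who dies during the final cycle does not
complete it, a cohort with certain death in cycle 120 accumulates exactly
119 discounted life years — the 119-payment annuity
`(1 - 1.03^-119)/0.03` — and the test suite pins the engine to that closed
form at `1e-9`.

## Background adult mortality by life-table matching

Survey data give region-specific mortality only under age five. Adult
mortality is proxied by assuming that a region with the under-five
mortality of the nation at some historical period also has that period's
adult mortality: each region is matched to the reference abridged life
table whose under-five mortality (U5MR) is nearest the region's reported
2016 U5MR (ties break toward the lower-U5MR table, so matching is
deterministic and order-independent). The matched abridged table is
expanded to single-year probabilities with a constant-hazard split within
each interval, `q_year = 1 - (1 - nqx)^(1/n)` — the standard
abridged-to-single-year convention, chosen because it is exactly
invertible (the expanded years multiply back to the interval probability
to machine precision). Ages past the terminal open interval carry the last
closed interval's annual probability forward, and the final modelled age
is forced to certain death so the cohort closes. The region's own infant
and child probabilities then overwrite ages 0–4.

The intended reference set is a family of national period life tables
(e.g. UN World Population Prospects abridged tables, which the reader
accepts as plain CSV). Because redistributing those tables is not
appropriate and the original analysis does not report which period was
matched to which region, the package ships a clearly-labelled *synthetic*
reference family instead: a base abridged table emulating Ethiopian
mortality around 2010–2015 (U5MR 0.068, life expectancy at birth 64.7
years) swept through 16 log-spaced hazard-power levels,
`nqx' = 1 - (1 - nqx)^f` for `f` between 0.35 and 3.0. The hazard-power
family was chosen because one parameter guarantees valid probabilities and
strictly monotone U5MR — matching is exactly testable — while moving child
and adult mortality together the way historical period tables do. The base
table was fixed on those demographic anchors; with it, the pipeline
reproduces the published per-region life-expectancy-gain pattern within
±0.15 years everywhere and the published cost-effectiveness ordering
(Addis Ababa cheapest, SNNP dearest). Absolute life-expectancy *levels*
depend on the reference family more than the increments do, so levels
should be read as approximate unless a real period-table set is supplied.

## Costs and cost-effectiveness

The unit cost of a treated episode is a residency-weighted average,
`45 * x + 45 * 7.2 * (1 - x)` USD for urban fraction `x`: 45 USD per
urban treatment, with rural delivery 7.2 times dearer. For the bundled
Ethiopian inputs the blended regional unit costs are taken as published
(urban fractions per region are not available); training and capital
costs are excluded.

The ICER divides incremental cost by incremental life years. Both
denominators are exposed: discounted life years (3%, the stated headline
convention) and undiscounted life expectancy, because the published
per-region figures are numerically consistent with undiscounted
denominators (e.g. unit cost / (CFR × efficacy × life expectancy) ≈ 26
USD/LY for Addis Ababa). A closed-form sanity oracle in the test suite
checks the undiscounted ICER against that approximation within 15% for
every region. Verdicts against a willingness-to-pay threshold use an
inclusive comparison at a configurable fraction of GDP per capita
(default 50% of 713 USD).

## Inequality metrics

Two weighted Gini coefficients (relative mean absolute difference,
`G = Σ w_i w_j |x_i - x_j| / (2 W² μ)`, computed by the exact
`O(n log n)` sorted form and pinned to an `O(n²)` brute-force oracle at
`1e-12` in tests; no small-sample correction, since weights are population
masses):

* **Interindividual**: ages at death from the cohort's deaths-by-age
  distribution, each death credited at its cycle midpoint `a + 0.5` so the
  mean age at death equals the half-cycle-corrected life expectancy.
  National values pool the regional deaths-by-age distributions weighted
  by births; the pooling convention is a package choice (a
  single-national-model alternative would differ) and is documented here
  because published values do not state theirs — treat printed anchors as
  approximate.
* **Geographical**: regional life expectancies weighted by regional birth
  cohorts.

## Scale-up strategies

Three static strategies (no roll-out sequencing, no budget constraint):

* `health_max` — the `k = 5` regions with the lowest ICER. The source
  analysis says "six regions" but names five, and the published scenario
  cost matches the five named regions' summed costs to within rounding;
  `k` is configurable.
* `equity` — the `k = 3` regions with the highest *reported* U5MR.
  Ranking uses the survey-reported U5MR column, not U5MR recomputed from
  the model inputs: the recomputed ranking would swap Somali out of the
  top three, contradicting the published selection. Both sources are
  available (`match_on`/ranking options).
* `universal` — all regions.

Selected regions run at target coverage, the rest stay at baseline, and
national aggregates are birth-cohort-weighted. Birth cohorts are not
published; the bundled values are synthetic rough estimates (regional
population projections × regional fertility, normalized to ≈3.27 million
national births) and all ratios that matter — ICERs, cost per death
averted, Gini coefficients, weighted LE gain — are invariant to the
cohort scale, which the tests assert. An externally supplied cost table
(e.g. the published rounded program costs) can replace model-computed
incremental costs in scenario aggregation for exact-arithmetic checks.

## Synthetic data generation

`synthetic_regions()` draws region tables uniformly from the observed 2016
spans (incidence 0.04–0.46 episodes/child-year, coverage 0.25–0.60, infant
mortality 16–77 per 1000, child mortality 1.7–11.5 per 1000), derives unit
costs from drawn urban fractions, and sets `reported_u5mr` consistent with
the drawn probabilities so equity ranking is well-defined. Generation is
deterministic under a fixed seed, and the unit-cost parameters are exactly
recoverable from generated tables (a parameter-recovery test).

What synthetic data do *not* emulate: survey sampling error, spatial
correlation between incidence and mortality, or real historical age
patterns of mortality (the hazard-power family moves all ages together).
Passing tests on synthetic data therefore demonstrate correctness of the
machinery and reproduction of the published *patterns*, not validation
against real adult mortality.

## Numerical choices and degenerate inputs

* Probabilities are validated into `[0, 1]`; counterfactual mortality is
  clamped to `[0, 1]` with a warning naming the region rather than an
  error, so extreme synthetic inputs degrade gracefully.
* Zero incremental effect raises a distinct "no incremental effect" error;
  negative (dominated) a distinct "dominated" error. Decremental scale-up
  (target below baseline) is refused.
* Life-table matching tie-breaks to the lower-U5MR table; ranking
  tie-breaks alphabetically on region name. All pipeline outputs are
  bit-reproducible run-to-run.
* Machine outputs are written at full precision (17 significant digits in
  CSV, exact JSON); presentation rounding lives in a separate helper,
  because published tables' own SUM rows show what rounding before
  summation does.

## Problem sizes

Everything runs at the analysis's natural size: 11 regions × 2 arms × 120
annual cycles, a 16-table reference family, and property tests over a few
hundred random instances. The full test suite completes in a few seconds
on one CPU.

## Worked example

```{r example}
fx <- ethiopia_fixture()
refs <- ethiopia_reference_set()
run <- suppressWarnings(run_all(fx$regions, refs, fx$params))
pretty_report(run$table[, c(
  "region", "le_baseline", "le_target", "incremental_le",
  "icer", "icer_undiscounted"
)])

sc <- suppressWarnings(run_scenarios(fx$regions, refs, fx$params))
pretty_report(sc$table)
```

## Known limitations

* No morbidity states, disability weights, or post-episode sequelae; the
  effect measure is mortality only.
* No probabilistic sensitivity analysis; the model is a deterministic
  expectation.
* Absolute life-expectancy levels inherit the synthetic reference family's
  shape unless the user supplies real period life tables
  (`read_life_table_dir()`).
* Unit costs rest on a single rural-to-urban cost ratio transported from a
  neighbouring country's delivery system; demand-generation costs are
  excluded.
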