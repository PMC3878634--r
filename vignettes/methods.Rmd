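---
title: "Diet pattern modeling of sodium and potassium feasibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet pattern modeling of sodium and potassium feasibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietlp)
```

## The problem

US dietary guidance asks most adults to keep sodium below 2300 mg/d (1500
mg/d for older and at-risk groups) while consuming at least 4700 mg/d of
potassium — an implied Na:K mass ratio of about `round(2300/4700, 2)` =
0.49. Whether *any* realistic diet can satisfy both targets together with
full nutrient adequacy is a feasibility question, and linear programming
answers it exactly: treat a sex-age group's food categories as continuous
variables (g/d), impose energy, nutrient-adequacy and food-acceptability
constraints, and map the set of (sodium, potassium) totals that some
feasible diet attains.

`dietlp` implements that pipeline end to end: a seeded synthetic-data
generator standing in for intake-survey and food-composition databases
(which cannot be redistributed), exclusion filters and category
aggregation, a constraint builder, an LP core with an independent
brute-force oracle, a feasibility-region mapper, and a food-supply
perturbation scenario (an across-the-board 10% sodium cut).

## The model

For one sex-age group with categories $i = 1,\dots,n$, per-100 g profile
vectors $p_i$ and amounts $x_i \ge 0$ (g/d):

* **Energy equality.** $\sum_i e_i x_i = \mathrm{EER}$, the group's energy
  requirement. Equality — not a range — so patterns are comparable across
  groups and scenarios.
* **Nutrient rows.** For each Dietary Reference Intake entry, a row
  $\sum_i a_{ji} x_i \ge \mathrm{RDA}_j$ or $\le \mathrm{UL}_j$.
* **Consumption (acceptability) bounds.** Each of the 9 major food groups
  is bounded by the observed 10th and 90th percentiles of daily
  consumption in the group; each subgroup and category is bounded above by
  its observed 75th percentile. These keep optimized patterns inside the
  envelope of observed eating habits.
* **Na:K ratio.** Optionally, $\mathrm{Na}(x) - r\,\mathrm{K}(x) = 0$ with
  $r = 0.49$ by default. Implemented as an equality (an inequality mode is
  a config switch) because the analyses hold the ratio *constant*.
* **Fixed sodium.** Optionally $\mathrm{Na}(x) = s$; the sweep device.

Two objectives are used. **Max-K** maximizes $\mathrm{K}(x)$, either on the
ratio line (the anchor point) or at fixed sodium (the sweep). **Min
deviation** minimizes $\sum_i w_i |x_i - o_i|$ where $o$ is the group-mean
observed pattern, linearized with split variables
$x_i - o_i = d^+_i - d^-_i$. Weights default to $w_i = 1/o_i$ (relative
deviations; $1/\bar o$ for never-consumed categories), with plain L1 as an
alternative — the literature this deviation objective descends from does
not pin a unique functional, so the choice is documented rather than
claimed.

### The feasibility region

With the ratio constraint removed, sodium is fixed at levels marching down
(and up) from the anchor in 100 mg (0.1 g) steps until the LP first turns
infeasible; at each feasible level both a max-K and a min-K LP are solved,
so the region closes into a plottable band (the min-K lower envelope is
this package's construction; only the upper envelope is guideline-relevant).
The projection of a polytope onto (Na, K) is convex, so feasible levels form a
contiguous interval, the upper envelope is concave and the lower convex;
the test suite asserts all three, plus LP re-checks of interpolated
points.

### The 10% sodium scenario

Scaling every category's sodium by $m \in (0, 1]$ maps any feasible pattern
with totals $(s, k)$ to one with $(m s, k)$ and vice versa. The scenario
region is therefore *exactly* the baseline region under
$(\mathrm{Na}, \mathrm{K}) \to (m\,\mathrm{Na}, \mathrm{K})$ — asserted at
grid resolution in the acceptance tests — and the interesting question is
how the shifted region sits against the fixed guideline lines.

## The solver

No LP package is installed in the target environment, so the package ships
a dense two-phase tableau simplex (Rcpp) with deterministic pivoting:
Dantzig's rule with lowest-index tie-breaks and a Bland fallback to rule
out cycling. Determinism of the pivot path is how reproducibility of
degenerate optima is achieved; a planned secondary lexicographic objective
was dropped as redundant given deterministic pivoting. The solver is
cross-checked in the test suite against `boot::simplex` on random dense
LPs and against an exhaustive grid oracle on the registered toy fixtures.
The shared feasibility tolerance is 1e-6 (relative).

The brute-force oracle solves the equality rows (energy, ratio, fixed
sodium) exactly for a QR-pivoted set of dependent variables and scans the
remaining free variables on a regular grid in 100-g portion units
(`grid_step = 0.01` is 1 g), keeping candidates that are nonnegative and
satisfy every inequality at tight tolerance. Equalities hold exactly at
every candidate, so grid spacing is the oracle's only error; it converges
to the LP optimum as the step shrinks and shares no code with the simplex
path.

## The synthetic world

The generator emulates the structure the pipeline needs, not any real
database. Stated choices:

* **Taxonomy**: 9 USDA-style major groups, 39 subgroups, 110 categories by
  default; survey-specific variable counts of roughly 85–128 arise after
  group-specific pruning of unconsumed categories, and the total is an
  explicit parameter rather than a fixed constant.
* **Composition**: per-100 g energy, sodium and potassium are
  mean-preserving log-normals around per-major-group templates (e.g.
  vegetables 35 kcal, 45 mg Na, 290 mg K; grains 270 kcal, 450 mg Na, 120
  mg K). Sodium's log-sd of 1.0 encodes the large within-group spread of
  real composition data (raw vs processed); the LP's ability to compose
  low-sodium patterns depends on it. DRI-panel nutrients are placed per
  100 g with concentration multipliers (vitamin C in produce, calcium in
  dairy, B12/zinc/selenium in meat, vitamin E in oils), calibrated so
  ordinary mixed diets land modestly above adequacy minima — the property
  real surveys show. The DRI table itself is a documented synthetic
  stand-in; only the vitamin E override (13 mg/d), the sodium limits
  (2300/1500 mg/d) and the potassium goal (4700 mg/d) are fixed by the
  modeled guideline context.
* **Intakes**: one day per individual (matching the modeled survey); 20–60
  foods each, popularity-weighted, log-normal grams rescaled so total
  daily energy hits a target drawn around the group EER (CV 25%). Energy
  from foods that survive the exclusion filters therefore sits a few
  percent below the EER — the same relationship the real survey shows
  between observed group energy and the requirement. EER defaults:
  2700/2400/2000 kcal (men 20–30/31–50/51+), 2100/1900/1600 (women). 2% of
  individuals are pregnant (women) and 2% report under 600 kcal/d, to
  exercise the filters.

With these defaults the synthetic world reproduces the qualitative
structure of the real analysis: observed Na:K ratios near 1.2, nonempty
feasibility regions at ratio 0.49 for all six groups, maximal potassium
rising with energy requirement (so low-EER groups fail the 4700 mg goal
first) and the minimum attainable sodium rising with energy requirement
(so high-EER groups fail a tightening sodium limit first).

What a green test does **not** establish: anything about real NHANES/FNDDS
magnitudes. The synthetic world has no survey weights, no multi-day
intake, no item-level realism beyond the moments described above; numeric
region boundaries are properties of the stated world only. Properties that
are data-independent (the affine sodium-scaling map, convexity of the
projection, oracle/solver agreement, the min-deviation zero-iff-feasible
identity) are the portable results.

## Numerical and design choices

* Percentiles use linear interpolation between order statistics (R type
  7), stated so the test oracles match. Major-group percentiles include
  non-consumers as zeros (a population-level bound); subgroup/category
  p75 is over consumers only, since it bounds *observed consumption*.
  Both are switchable.
* "Frequency of occurrence" weighting in category aggregation is total
  grams consumed — it conserves nutrient mass exactly and is well defined
  with one-day data.
* The 600 kcal/d exclusion is evaluated on energy from foods that survive
  the food filter, which makes the two filters commute.
* Guideline rows (Na ≤ 2300/1500, K ≥ 4700) are constructor options, off
  by default, because the sweep and ratio analyses replace them; the UL
  row stays inactive during sweeps.
* The sweep starts at the anchor sodium level from the ratio run
  (config-overridable) and records the first infeasible level on each
  side.
* Degenerate inputs: empty groups, empty category lists, taxonomy
  mismatches, min > max DRI rows, negative fixed sodium and out-of-range
  multipliers are rejected with explicit messages; unbounded models are
  reported as a modeling error rather than silently clipped.

## Limitations

* The solver is a dense tableau simplex: right for hundreds of variables,
  wrong for thousands; no sparse or revised factorization.
* The min-K lower envelope and the exact deviation weighting are design
  choices of this package, documented above rather than inherited.
* Synthetic consumption is independent across individuals and foods given
  popularity; no correlation structure (meal patterns, substitution) is
  modeled.
* One intake day per individual; usual-intake estimation is out of scope.
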