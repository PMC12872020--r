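---
title: "Assessing and diversifying urban forests with CanopyPlan"
author: "CanopyPlan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing and diversifying urban forests with CanopyPlan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CanopyPlan)
```

## The problem

Municipal tree inventories — one row per publicly owned stem with species,
diameter at breast height (DBH), dates and coordinates — make it possible to
ask two questions at the scale of a street, park or neighbourhood: *how
diverse and valuable is the canopy we have*, and *what should we plant next
so that it becomes more resilient*? CanopyPlan answers both with a small set
of transparent, reproducible computations. Resilience is operationalised as
**functional diversity**: species are binned into ten functional groups
(labels `1A`–`5`) built from trait profiles (seed size, specific leaf area,
leaf nitrogen, wood density, shade/drought/flood tolerance). The grouping is
taken as a fixed lookup shipped in the species catalog; re-deriving groups
from trait data is out of scope.

## Diversity model

For an abundance vector $n_1,\dots,n_S$ with proportions $p_i$, the package
reports richness $S$ and the exp-Shannon effective number

$$ \mathrm{EN} = \exp\Big(-\sum_i p_i \ln p_i\Big), $$

the Hill number of order 1, with the natural logarithm. At the species level
this is the effective number of species (ENS); at the group level, the
effective number of functional groups (ENFG), which lies in $[1, 10]$.
ENFG maps to qualitative bands; the printed band boundaries ("1 to 3", "3 to
5", ...) overlap at their endpoints, so the package adopts lower-inclusive
half-open intervals $[1,3)$, $[3,5)$, $[5,8)$, $[8,10]$ — an exhaustive,
non-overlapping cover of the scale. Composition risk uses the 10-20-30 rule
(and the stricter 5-10-15 preset); "no more than 10%" is read as *allowing*
exactly 10%, so a violation requires a strictly larger share. Proportions
are computed over the trees actually carrying the relevant taxonomy field,
and trees with missing fields are excluded from that rule's denominator.

## Biomass and carbon

Aboveground dry biomass is predicted per compartment $j \in \{\text{wood},
\text{bark}, \text{branches}\}$ by a DBH power law $y_j = \beta_{1j}
D^{\beta_{2j}}$ and summed; the regression error terms are taken as zero, so
compartments add exactly. Root biomass follows the wood type: softwoods
$RB = 0.222\,AB$, hardwoods $RB = 1.576\,AB^{0.615}$ (kg). Because
open-grown city trees carry less biomass than forest-derived equations
predict, the total is multiplied by an urban factor of 0.8, then by a carbon
fraction of 0.5, and valued at 994.57 CAD (2025) per ton of carbon — the
social cost of carbon. All three constants live in `carbonConfig()`. The
urban factor and the carbon fraction are scalar multipliers, so their order
of application cannot change the result; the implementation applies the
urban correction first. Monetary values stay unrounded internally; reports
round to whole CAD, and all reported rounding is half-away-from-zero
(`roundHalfAway()`), the convention under which the bundled reference tables
reproduce exactly (base R's round-half-even does not reproduce them).

Coefficients are **data, not code**: they ship as a versioned CSV and any
species missing from the table falls back to the generic `hardwood` or
`softwood` rows. The bundled `allometry_default_synthetic.csv` contains
representative temperate-zone magnitudes so the pipeline runs out of the
box; it is deliberately labelled synthetic and should be replaced by fitted
regression estimates for real valuation work. Trees with a missing DBH are
kept for every diversity computation but skipped (and counted) by the carbon
pipeline.

## Old-tree proxy

A species' "max DBH" is the 95th percentile of its DBH distribution in a
large reference inventory, computed with linear interpolation between order
statistics (the percentile and the minimum cohort size of 150 trees are
configurable in `maxDbhConfig()`). Species with smaller cohorts receive the
unweighted mean of same-genus species thresholds — averaging thresholds, not
pooling raw diameters, so a large sibling cohort cannot swamp a small one. A
tree is flagged old when its DBH is at or **above** the threshold: the
threshold is itself an observed high quantile, so the boundary tree is by
construction among the largest. Because the question "old trees are mostly
in which groups?" differs from "which groups are mostly old?", both
normalisations are reported (`share_of_old` and `old_within_group`).

## Recommendation and simulation

Candidates are catalog species that are plantable (not invasive, not
pest-excluded), belong to an included functional group, and would leave the
inventory rule-compliant **after** their own addition: the check uses
post-addition shares $(c+1)/(n+1)$, which prevents recommending a species
already sitting exactly at its cap. Each candidate is then scored one-shot
against the original inventory: one hypothetical tree at the fixed planting
DBH (15 cm, a nursery-stock assumption) is added, the five criteria — ENFG,
group richness, ENS, species richness, carbon — are recomputed, and the
relative improvements $x_i = n_{i,1}/n_{i,0} - 1$ are combined into
$\sum_i w_i x_i$ with the two functional-group weights fixed at 10 and the
other three user-set in $[1,10]$. Ties sort alphabetically by scientific
name, making the ranking fully deterministic and permutation-invariant.
Greedy re-scoring after each planted tree is intentionally not offered: the
planting procedure ranks once, takes the top 10, and splits the budget
(`round-half-away(fraction × n)` trees, default fraction 5%) evenly with the
remainder handed out from the top — matching how the published ten-park
scenario allocates its trees. If the carbon baseline is zero (no tree has a
DBH) the carbon criterion is reported unavailable and contributes zero to
the score rather than poisoning it. Scoring demands a nonempty inventory;
a single-species inventory is fine (all baselines are ≥ 1).

Simulation rebuilds the augmented inventory from scratch — planted trees
inherit taxonomy, group and wood type from the catalog, carry the fixed DBH
and no coordinates (they are invisible to spatial selection until planted
for real) — and reports before/after values with percent improvements to one
decimal. The tests verify that these from-scratch values agree with the
incremental arithmetic used during scoring on complete candidate sets of
small (≤ 50 trees) fixtures.

## Synthetic inventories

`generateSyntheticInventory()` is first-class, tested code that emulates the
municipal CSV: a functional-group mix (default uniform over the catalog's
groups; `balanced = TRUE` gives exact largest-remainder proportions), species
uniform within the sampled group, lognormal DBH with median ≈ 17 cm and
log-sd 0.6 — a young urban canopy in which more than half the stems stay
under 20 cm, as recent ambitious planting programs produce — and uniform
coordinates in a configurable box (default over Montreal). A fixed seed is
bit-reproducible down to the exported CSV. What it deliberately does *not*
emulate: spatial clustering of species along streets, genus-correlated DBH
distributions, measurement error, or missing-data patterns of real
inventories — so green tests demonstrate the correctness of the arithmetic
on realistic marginals, not robustness to real-world messiness.

## Numerical and interface choices

* Percentiles: type-7 linear interpolation; configurable.
* Point-in-polygon: even-odd ray casting with an explicit on-segment test so
  boundary points are *included*; coordinates are treated as plain WGS84
  lon/lat without projection (adequate at neighbourhood scale; do not use
  for regions crossing the antimeridian).
* Degenerate inputs: empty distributions raise a domain error for effective
  numbers and callers report richness 0; improvement is undefined for a
  non-positive baseline; an empty inventory passes every composition rule
  and lets every eligible candidate through the filter.
* Reports carry the tool version, seed and an MD5 hash of the invocation
  configuration, and contain no timestamps, so identical invocations are
  byte-identical.
* Problem sizes in the test suite: fixtures of 3–300 trees for unit
  behaviour, 10,000 trees for the sampling-error check that a uniform group
  mix drives ENFG to within 2% of its maximum — sizes at which every
  property can be recomputed from scratch by an independent oracle.

## Known limitations

Planted trees are frozen at 15 cm DBH — no growth model, so simulated carbon
improvements are conservative lower bounds on what maturing trees deliver.
Only carbon among ecosystem services is quantified (no heat-island or
stormwater benefits). The ten-group classification targets northeastern
North American urban floras; applying it elsewhere requires a regional
catalog. Recommendations ignore site suitability, nursery availability and
cost, which real planting programs must overlay.
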