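---
title: "The site suitability model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The site suitability model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubsite)
```

## The problem

Rural regions have small, dispersed populations, long drives between
communities, and thin specialist coverage. Dedicated palliative care in such
regions is rarely feasible as a stand-alone service; a more realistic
strategy is to enhance an existing rural community's health services into a
*secondary palliative care hub* (SPCH) — a site that delivers local
palliative care with remote specialist backup. The question this package
answers is *where*: given a region's communities, road network, existing
facilities and census-style attributes, which communities are the most
suitable SPCH candidates?

`hubsite` implements a four-component site suitability model (SSM). It is a
decision-support tool: the output is a ranked table with an eligibility
flag, plus the per-component scores that tell a planner *why* a community
ranks where it does.

## Candidate selection

Two filters reduce the universe of population centres to candidates:

1. **Population:** community population strictly greater than
   `min_population` (default 5000), so a hub would serve a sufficient base.
2. **Isolation from existing care:** network drive time from the community
   centroid to the nearest *palliative care centre* strictly greater than
   `catchment_minutes` (default 60). A palliative care centre is a general
   hospital with more than 500 beds or a dedicated hospice with more than 3
   hospice beds — both strict inequalities, read literally from the
   definitions the model was developed with; a 500-bed hospital does not
   qualify.

A community that cannot reach any palliative care centre at all is treated
as maximally isolated and passes the second filter: unreachability is a
first-class value (`Inf`) throughout the travel-time engine, never an error.

## The travel-time engine

Roads are supplied as line segments with `length_km` and `speed_kmh`
attributes; each becomes one undirected edge weighted by its traversal time
`60 * length_km / speed_kmh` minutes. Segment endpoints are the nodes;
endpoint coordinates are rounded to 1 mm, and coincident endpoints merge,
which is how intersections connect the graph. Shortest paths, service areas
and nearest-facility queries are Dijkstra runs over this graph (via
**igraph**).

Deliberate simplifications, chosen for sparse rural road data and documented
here loudly:

* **No one-way streets.** Rural segment data rarely carries directionality;
  travel time is symmetric.
* **Free off-network access.** Communities, blocks and facilities snap to
  their nearest node at zero cost; ties break to the lexicographically
  smallest node identifier so results are deterministic.
* **No reprojection.** All inputs must already share one planar metric
  coordinate system. The package contains no geodesy on purpose.
* **Catchments from centroids.** Every travel-time quantity is computed from
  the community's snapped centroid node, not from its boundary.

Turn restrictions, congestion, time-of-day speeds and ferry links are out of
scope.

## The four components

Each component is a score in $[0, 1]$ per candidate community.

**Population** — total population of the census-style blocks whose snapped
node lies within the 60-minute service area of the candidate. The largest
catchment scores 1 and the rest scale proportionally:
$P_i = \mathrm{pop}_i / \max_j \mathrm{pop}_j$. The score is invariant to
rescaling all catchments by a common factor.

**Isolation** — drive time $t_i$ to the nearest palliative care centre,
scaled against a cap $T$ (default 240 minutes):
$I_i = \min(t_i / T,\, 1)$, with $I_i = 1$ when unreachable. Non-decreasing
in $t_i$ and constant at 1 beyond the cap.

**Vulnerability** — a palliative care index: the mean of four equally
weighted sub-scores, each scaled over a reference set of communities —
percentage of population over 75, percentage female, percentage living
alone, and a deprivation composite:
$V_i = (\mathrm{age}_i + \mathrm{sex}_i + \mathrm{alone}_i +
\mathrm{vandix}_i)/4$.

**Readiness** — five binary indicators of fit, each worth 0.2: a local
hospice society, a college or university within reach, regular telemedicine
use, adequate family-physician supply, and expressed momentum towards a
local hospice. Computed as `sum(flags) / 5`, which is exact on the 0.2 grid
in binary floating point (five times 0.2 is not).

Physician-supply adequacy means at most 1307 persons per family physician —
an **inclusive** boundary, per the benchmark's wording — computed from the
community's own population and physician count. We use the community
population rather than the catchment population because the benchmark is a
practice-ratio statistic defined on the population a physician roster
actually serves; an explicit `fp_adequate_override` column takes precedence
when supplied, mirroring how such flags are compiled by hand in practice.

### Scaling modes and the reference set

The model's narrative description says the community with the highest raw
value of each vulnerability variable "is assigned a 1", i.e. max-scaling —
yet published sub-score tables (e.g. percent-female sub-scores of 0.42–0.51)
are numerically consistent with raw proportions, not max-scaling. Rather
than silently resolving this contradiction we surface it:
`pcix_scaling_mode` is configurable (`"max"` — the default, following the
text; `"minmax"`; `"none"` — raw values clipped to $[0,1]$, which is what
reproduces the published sub-score tables from raw proportions).

The reference set over which variables scale is also configurable: a
supplied province-wide table when given (`reference` argument of
`run_ssm()`), otherwise the candidate set itself.

### The deprivation composite

The deprivation composite is specified as seven dissemination-area
indicators, but its source documentation enumerates only six (incomplete
high school, unemployment over 15, lone-parent families, average total
income, homeownership, employment ratio). We therefore implement seven
indicator *slots* (`vx_1 .. vx_7`) and do not hard-code a guess for the
seventh; it defaults to deprivation-direction and is documented as the
user-configurable slot. Income, homeownership and employment ratio are
protective — higher raw values mean *less* deprivation — so after scaling
they are complemented ($1 - s$). The direction handling is not part of the
published description; it follows from the composite being a deprivation
index, and the direction vector is a visible, overridable parameter
(`vandix_directions`).

## Aggregation, rounding, ranking

The final score is the weighted mean $S = \sum_k w_k s_k / \sum_k w_k$; with
the default equal weights this is exactly the sum of the four components
divided by four. Normalizing by $\sum w$ generalizes the published
equal-weight rule so any non-negative weight vector yields a $[0,1]$ score —
reweighting by local stakeholders is an intended use of the model.

All internal arithmetic is kept at full precision; rounding happens only at
the display/serialization boundary. Display rounding is **half away from
zero on decimal digits** (`round_display()`): 0.325 prints as 0.33. This is
the convention under which the published score tables reproduce exactly
(two of the twelve worked-example rows — totals of 0.335 and 0.325 — round
the wrong way under IEEE round-half-even). The implementation prints the
double at 12 decimals first, recovering the intended decimal value, then
rounds the digit string.

Eligibility is *strict*: a community is flagged when its score exceeds the
0.6 cut-point; boundary equality is ineligible. Ranking sorts by score
descending; exact ties break by population component descending, then
community identifier ascending. The tie-break is an artifact convention —
the model itself reports identical scores without ordering them — but it
makes rankings deterministic and permutation-invariant.

Known worked-example caveat: three of the twelve published vulnerability
rows (Haileybury, Hawkesbury, Parry Sound) print totals that disagree with
their own printed sub-scores at two decimals (0.35 vs 0.34, 0.29 vs 0.28,
0.32 vs 0.30). The test suite asserts exact reproduction only for the nine
self-consistent rows and a ±0.02 band for those three.

## The synthetic-region generator

Licensed census and road datasets cannot ship with the package, so every
stage is exercised on generated regions (`generate_region()`) and on a fixed
hand-traced fixture (`generate_line_region()`).

The generator emulates the *structure* the model assumes, not any actual
geography: a perturbed square lattice of roads (rural road networks are
approximately planar grids; random planar triangulations were rejected as
heavier machinery with no testing benefit), thinned by randomly dropping
edges only when connectivity survives; blocks scattered around nodes;
centres with log-normal populations and Beta-distributed demographic
proportions; facilities of both kinds with log-normal hospital bed counts
(large hospitals are rare, as in real rural regions) plus one guaranteed
qualifying regional hospital. Defaults: an 8×8 grid at 25-km spacing —
chosen so a 60-minute catchment spans roughly two grid steps and the
region's diameter comfortably exceeds the 240-minute isolation cap, the
geometry in which the model's filters are meaningful — edge keep-probability
0.85, speeds 50–90 km/h, 15 centres (population median ~9000, log-sd 0.7),
150 blocks, 5 facilities, readiness flag probability 0.5.

A single master seed drives everything through per-layer sub-streams, so
adding a layer does not perturb the others and output files are
byte-identical across runs and platforms for identical parameters.

What passing tests on synthetic regions do **not** show: real road networks
have directional links, grade-separated crossings and ferries; real census
marginals are spatially autocorrelated; real readiness flags are compiled
from phone calls and websites. Results on generated regions validate the
computational contract, not the model's empirical adequacy in any province.

The line fixture is six communities on a single 60 km/h road with a 600-bed
hospital at one end; every intermediate quantity — travel times (40, 90,
160, 220, 310 minutes cumulative), the selection outcome, catchment sums,
all four components and the final ranking — was worked out by hand and
frozen in `line_region_expectations()`, giving an end-to-end oracle that is
independent of the implementation.

## Numerical and degenerate-input choices

* Empty catchments everywhere → all population scores 0 (no division by a
  zero maximum).
* Degenerate scaling ranges (all-equal reference values under min–max, or an
  all-zero column under max-scaling) → sub-scores 0, with a warning for the
  single-community case.
* No qualifying palliative care centre → the isolation filter is vacuous;
  all population-qualified communities pass, with a warning.
* Missing readiness flags default to "no" with a warning rather than an
  error, because such flags are compiled manually and are often incomplete.
* Weights must be non-negative with positive sum; `weights = c(0,0,0,0)` is
  a validation error, not NaN.

## Problem sizes

The shipped tests run the travel-time engine against a brute-force
Floyd–Warshall oracle on 100 random graphs of up to 12 nodes, the full
pipeline on the line fixture, property checks on 5 seeded regions of a 5×5
grid, and 50 seeded facility-addition trials on 4×4-grid regions; the
acceptance script runs one 6×6-grid region of 10 centres and 60 blocks.
These sizes give complete oracle coverage of the graph engine and
non-degenerate candidate sets at every stage while keeping the whole suite
fast; the engine itself handles much larger networks (cost is one Dijkstra
run per community per query).

## Limitations

The model is a screening tool. Component weights have no one-size-fits-all
calibration; the 0.6 cut-point is discretionary and should be revisited per
application; and the model does not capture context such as health-system
bureaucracy or coastal/ferry geography, where drive time under-represents
true isolation. The intended workflow is that local stakeholders reweight,
re-run and interpret the component scores, not just the final ranking.
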