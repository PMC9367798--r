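---
title: "Methods: security-constrained land-use simulation with lesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: security-constrained land-use simulation with lesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesim)
```

This vignette documents the models implemented in `lesim`, the choices
made where the methodology is genuinely open, and what the shipped tests
do and do not demonstrate.

## 1. The evaluation model

### Indicator system and standardization

Land ecological security is scored per grid unit from a
pressure–state–response indicator system: pressures (fertilizer and
pesticide intensity, population growth, urban expansion), state
(land-cover quality, economic condition, resource reserves) and response
(pollution treatment, environmental investment, engineering governance).
The package ships a 3-criteria / 9-factor / 19-indicator tree
(`psr_hierarchy()`, metadata in `psr_indicators()`); any other hierarchy
can be declared as a nested list or YAML file.

Benefit-type ("positive") indicators are standardized as
$H = (x - \min x)/(\max x - \min x)$ and cost-type ("negative")
indicators as $H = (\max x - x)/(\max x - \min x)$, so every leaf lies in
$[0,1]$ with 1 always the ecologically favourable end. A constant column
cannot be standardized and is rejected; degenerate synthetic tables
surface this error deliberately.

### Entropy weights

Indicator importance is data-driven: with $p_{ij} = H_{ij}/\sum_i
H_{ij}$, entropy $e_j = -(\ln m)^{-1}\sum_i p_{ij}\ln p_{ij}$ (with
$0\ln 0 := 0$) and weight $w_j = (1-e_j)/\sum_k(1-e_k)$. A column
constant across units carries no information and receives weight zero;
all-zero columns are shifted by $10^{-4}$ before proportioning so the
entropy is defined. This is the canonical formulation of the entropy
weight method; no alternative weighting (AHP etc.) is provided.

### Catastrophe-progression aggregation

The weights do not enter the aggregation arithmetic — they *rank*
children at each node (`rank_children()`), an internal node's importance
being the sum of its descendant leaf weights, ties keeping declaration
order. The k-th ranked child value $v$ is normalized by the root exponent
of its control-variable slot, $v^{1/(k+1)}$: fold ($\sqrt a$), cusp
($\sqrt a, \sqrt[3] b$), swallowtail (adds $\sqrt[4] c$) and butterfly
(adds $\sqrt[5] d$). Nodes combine normalized children by the
complementary principle (mean) by default; the non-complementary
principle (min) is a per-node override for uncorrelated controls. Nodes
with more than four children are rejected rather than split, since only
the four canonical models exist; the shipped hierarchy never exceeds
three.

Aggregation is monotone in every leaf and maps $[0,1]^p \to [0,1]$,
which the test suite verifies on a thousand random hierarchies.

### Index adjustment and zoning

Raw CPM indices crowd near 1 (on synthetic data the full range is
typically 0.92–0.97), so equal-width grading is useless. The package
follows the affiliation-level adjustment: reference levels $n_0,\dots,
n_{10}$ are produced by pushing the uniform leaf values $0, 0.1, \dots,
1$ through the ranked hierarchy ($n_0 = 0$, $n_{10} = 1$, strictly
increasing), and a raw index $L \in [n_i, n_{i+1}]$ is re-expressed
relative to its decile. The printed form of this adjustment,
$L' = (L-n_i)/(n_{i+1}-n_i)\times 0.1$, maps *every* decile onto
$[0, 0.1]$ and therefore destroys global ordering; classifying such an
index by natural breaks would be ill-defined. The package's default
("monotone") variant adds the offset $i \times 0.1$, giving a
piecewise-linear, order-preserving map onto $[0,1]$; the offset-free
formula is retained behind `variant = "verbatim"` for users who want the
literal published form within deciles. This was a genuinely open design
point; the monotone variant is the only one under which the downstream
zoning is well-posed, which is why it is the default.

Zoning cuts the adjusted index into four classes with exact Fisher–Jenks
dynamic programming (deterministic, unlike the heuristic iterative
variant), validated against exhaustive partition enumeration for
$n \le 15$, $k \le 4$. Boundary convention: the ecological core zone is
open below (strictly greater than the top break); every lower class is
closed at its upper break. Values below the observed minimum clamp into
the urban development zone. Reported raw-unit thresholds are the minimum
raw index observed in each class, since classification operates on the
adjusted index but raw-unit cutoffs are the customary reporting scale.

## 2. The simulation model

### Transition matrix and demand

`transition_matrix()` estimates $P[u,v]$ as the fraction of class-$u$
cells at the base date that are $v$ at the later date; classes absent at
base carry identity rows. Demands are integerized per source row by
largest-remainder rounding of $\mathrm{base}_u P[u,\cdot]$, so row sums
(and hence the study-area cell count) are conserved exactly.

### Constraint-factor weights

For each class, presence/absence cells are sampled without replacement —
$\lfloor f n_1 \rfloor$ class cells and $\lfloor f n_0 \rfloor$ others at
the default fraction $f = 0.05$ — from the *end-period* map (presence at
period end; sampling from the start map is the other defensible reading,
and an include-list lets users reproduce a-priori factor omissions).
Factors are screened by VIF/TOL ($\mathrm{VIF}_j = 1/(1-R_j^2)$, flag at
VIF ≥ 10), z-scored so coefficient magnitudes are comparable across
units of measure, and fitted by maximum-likelihood logistic regression
(tolerance $10^{-8}$, 100 iterations). Perfect separation — detected by
boundary fitted probabilities as well as by glm warnings — triggers a
flagged ridge-penalized ($\lambda = 10^{-6}$) IRLS refit. Factors with
Wald $p \ge 0.05$ are dropped; the remaining absolute standardized
coefficients are normalized to unit sum, the coefficient sign being
carried separately to orient each factor's fuzzy membership. How
published constraint weights derive from logistic output is not uniquely
determined; unit-sum normalized |coefficient| with a separate sign is the
least-machinery rule that reproduces unit-sum signed weight rows.

### Suitability atlases

Per class, suitability is
$Q = R \times \sum_i w_i f_i$: $R$ a Boolean restriction mask (cells
already of the class, permanent basic farmland, water and construction
at base; under the ecological-protection scenario the ecological core
zone additionally closed to construction), and $f_i$ linear min–max
memberships oriented by each factor's sign. Memberships are linear
rather than sigmoidal because min–max standardization is the form used
elsewhere in the framework; values are kept as floating point in
$[0,1]$ rather than byte-quantized. The restriction phrase "the k-type
land" is read as *excluded from conversion to k* (the MCE convention);
protection of basic farmland, water and built land is handled separately
by freezing those cells in the automaton, the only reading under which
farmland can keep existing on protected farmland cells.

### Allocation

The automaton distributes each from–to demand linearly over $T$ cycles
(cumulative target at cycle $t$ is the largest-remainder rounding of
$t/T$ of the pair total). Within a cycle, gaining classes are processed
in descending remaining demand; candidate cells of the losing class are
ranked by $Q_v \times (\varepsilon + h_v)$ with $h_v$ the fraction of
the 5×5 edge-truncated window in class $v$ and $\varepsilon = 0.01$ so
isolated high-suitability cells remain reachable; ties fall to (row,
col) order; a cell changes at most once per cycle; frozen and
zero-suitability cells never change. Whether the classic contiguity
filter multiplies or gates suitability is not documented anywhere
authoritative; the multiplicative form with an $\varepsilon$ floor is
declared package behaviour, chosen for determinism and testability, and
verified cell-for-cell against a brute-force greedy oracle on small
grids. Infeasible demand (e.g. demanded losses from frozen water) is
allocated as far as eligible cells allow and the shortfall logged.

Ten cycles for a ten-year horizon mirrors one cycle per year, but
`cycles` is exposed independently of the horizon.

### Validation

Kappa is computed over the full-map census, not a sample:
$p_0 = \mathrm{tr}(M)/n$, $p_e = \sum_c r_c c_c / n^2$,
$\kappa = (p_0-p_e)/(1-p_e)$. Change tables and zone–land-use tables
report areas as cell counts × cell area in km² and percentages to two
decimals.

## 3. The synthetic world

The generator emulates the statistical structure the pipeline assumes —
not any real landscape. `synth_landscape()` grows contiguous class
patches from random nuclei by budget-capped dilation (re-seeding a class
whose patches get enclosed), hitting the class budget to within 2 % at
200×200; change to the second date applies per-pair drift intensities
preferentially at class boundaries, so estimated transition
probabilities recover the drift within rounding. Default conditions
sketch a rapidly urbanizing subtropical region on a 30 m grid: class
budget 28 % farmland, 40 % woodland, 4 % grassland, 8 % water, 18 %
construction, 2 % unused, and a decade of drift dominated by
farmland→construction (0.10) with minor woodland/grassland conversion —
one-time choices of realistic magnitudes, not tuning knobs.
`synth_drivers()` derives the four distance surfaces from synthesized
river/road/town/settlement masks via the exact Euclidean distance
transform, population as $5000\,e^{-DT/1500}$ plus Gaussian noise (sd
250), and elevation/slope as smooth gradient fields. `synth_indicators()`
draws the nineteen indicators per grid unit (default 20×20 units),
coupling the land-cover-share indicators (construction, woodland, water
proportions) to the actual landscape with 2-point noise. All randomness
flows from one spec seed through fixed per-component substreams, so
regenerating one component never perturbs another.

What passing tests on this world *do* show: exact arithmetic of every
operation, conservation, determinism, the EP guarantee (zero
construction gain in the core zone), and parameter recovery at stated
sample sizes. What they do *not* show: realism of any particular
landscape, transferability of fitted driver weights, or the accuracy of
any real-region forecast — those require real co-registered rasters.

## 4. Numerical choices and degenerate inputs

- Distances are planar centre-to-centre Euclidean (exact distance
  transform); no geodesic correction, adequate at city scale on 30 m
  cells. Grids are 0-based (row, col) with row 1 at the map top; nodata
  cells are excluded from every statistic, transition count and
  allocation.
- Largest-remainder rounding is used wherever real-valued demands must
  become integers; ties break by position, making every stage
  deterministic.
- Constant rasters cannot be fuzzified and constant indicator columns
  cannot be standardized; both raise errors rather than guessing.
- Fisher–Jenks is exact $O(kn^2)$ dynamic programming — fine for
  unit-level tables (hundreds to a few thousand values), not meant for
  millions of raster cells.
- Reference levels must be strictly increasing; a hierarchy violating
  this (impossible for valid models) is rejected.
- Problem sizes in the shipped tests — 200×200-cell worlds, 400
  evaluation units, $n = 5000$ logistic samples, 100-case oracle sweeps —
  were chosen as the smallest sizes at which the statistical assertions
  (±0.1 slope recovery, ±0.02 transition recovery, ±2 % class budgets)
  are comfortably stable.

## 5. Known limitations

- Raster I/O is ESRI ASCII grid only; GeoTIFF and reprojection are out
  of scope (align and export grids with GIS tooling first).
- The allocator is a deterministic greedy automaton, not a
  patch-growing engine (FLUS/PLUS) nor a faithful reimplementation of
  any proprietary multi-objective allocator.
- Only the natural-development and ecological-protection scenario pair
  is built in; other scenario families (farmland protection, over
  expansion) would enter through custom restriction masks and drift
  matrices.
- Demand comes from the one-step Markov projection; external
  system-dynamics demand models are not supported.
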