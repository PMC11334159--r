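---
title: "Spatial efficiency of packed connectomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial efficiency of packed connectomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypopack)
```

## The model

`hypopack` treats a set of brain regions as spheres in a common millimetre
coordinate frame. Each region contributes its measured volume $V_i$
(mm³), giving a radius $r_i = (3V_i/4\pi)^{1/3}$, and a center position
taken from its measured coordinates. The connectome is a directed,
non-negative matrix $I_{ij}$ of projection volumes (mm³) aligned to the
region order; it is asymmetric in general, so the wiring forms a directed
graph. Self-projections are excluded: the diagonal is forced to zero at
load.

Two scalar objectives summarize a configuration:

$$S = \sum_{i \ne j} \frac{I_{ij}}{d_{ij}} \quad \text{(mm}^2\text{)},
\qquad W = \sum_{i < j} d_{ij} \quad \text{(mm)},$$

with $d_{ij}$ the Euclidean center distance. $S$ — the *neural
efficiency* — is large when strong projections span short distances; $W$
— the *wiring cost* — measures total inter-region distance assuming
equal-caliber connections. $S$ runs over ordered pairs because $I$ is
directed; $W$ runs over unordered pairs because distance is symmetric
(an ordered-pair sum would only double every value and move no optimum).
Both choices are recorded in the result objects. Coincident centers with
a positive weight between them raise an error rather than returning a
huge finite $S$ (distances below $10^{-9}$ mm are treated as degenerate
geometry).

Geometry is summarized pairwise by the *signed separation*
$d_{ij} - (r_i + r_j)$: negative values are overlaps, positive values
gaps, zero is touching. Six statistics — total, mean and maximum overlap;
total, mean and maximum gap — are computed over **all** unordered region
pairs, not only connectome edges, since they describe geometry rather
than wiring. Means (and maxima) over an empty subset are defined as 0 so
the statistics stay well defined on overlap-free or gap-free packings.

## Preprocessing of tracing experiments

Atlas-style viral-tracing tables carry several replicate injection
experiments per source region. Two reduction rules are provided:

- `select_max_intensity_experiment()` keeps, per source region, the
  replicate with the greatest total projection volume summed over
  targets, breaking ties toward the lexicographically smallest
  experiment id so the choice is deterministic. Total projection volume
  is used as the intensity proxy because it is the quantity the model
  consumes.
- `average_injection_position()` places a region at the per-axis
  arithmetic centroid of its experiments' injection coordinates (the
  geometric center). A coordinate-wise geometric mean was rejected: it
  is undefined for non-positive coordinates, which arbitrary frames
  produce.

`remove_regions()` drops named regions (e.g. peripheral outliers far
from the tightly packed bulk) and slices the adjacency to the aligned
submatrix, preserving order — with 26 regions and 3 outliers removed the
analysis continues on a 23-region bulk and its 23×23 submatrix.

## Constrained repacking

`optimize_packing()` searches for sphere positions maximizing $S$ (or
minimizing $W$) subject to:

- every coordinate inside `box_bounds` (default [0, 15] mm, comfortably
  larger than a few-mm cluster; optima are insensitive to enlarging it);
- every unordered pair's overlap at most `epsilon_max` (default 0.8 mm,
  the overlap scale that sphere models of real anatomy exhibit).

Because a pair of small spheres with $r_i + r_j \le \epsilon_{\max}$
would face no constraint at all — and $S$ grows without bound as such a
pair collapses — the constraint is implemented as a per-pair minimum
center distance

$$d_{ij} \ge \max\!\big(r_i + r_j - \epsilon_{\max},\;
  f\,(r_i + r_j)\big), \qquad f = 0.05,$$

so no pair may approach closer than 5% of its combined radii
(`min_distance_frac`). The guard binds only where the overlap cap is
vacuous and keeps the maximization well posed.

The solver is an augmented-Lagrangian (Powell–Hestenes–Rockafellar)
outer loop over box-constrained L-BFGS-B inner solves, with analytic
gradients of both the objective and the constraints (verified against
finite differences in the test suite). Two numerical safeguards matter:

- The efficiency objective's $1/d$ terms are floored at half the
  per-pair minimum admissible distance. The floor lies strictly inside
  the infeasible region, so wherever the constraints hold the surrogate
  equals the true objective with exact gradients, while the augmented
  Lagrangian stays bounded below (without the floor, the $-S$
  singularity outruns any finite penalty).
- Maximization defaults to minimizing $-S$, which is better conditioned
  near $S \to 0$ than the inverse form; minimizing $1/S$ is available
  via `objective_form = "inverse"` and the two agree on the argmax on
  test instances.

Defaults: inner `ftol` $10^{-10}$ (relative), 400 inner iterations per
outer step, up to 50 outer steps, feasibility tolerance $10^{-6}$ mm. A
result is *converged* when the inner solver reports success and the
re-checked maximum constraint violation is below the feasibility
tolerance; nonconvergent restarts are kept and flagged, never dropped.
`run_restart_ensemble()` derives restart $k$'s start from seed
`master_seed + k` (stable across versions) and returns the distribution
of local optima. The efficiency landscape is multi-modal on densely
wired instances — distinct restarts genuinely reach distinct optima —
which is why the optimized reference is an ensemble, not a single
number.

## The random-packing null

`sample_ensemble()` draws geometry-matched null configurations by
rejection: centers are proposed i.i.d. uniform inside the reference
packing's bounding box (the box that *barely fits* every sphere surface;
`box_padding` widens it for sensitivity checks, default 0), and a
proposal is accepted when each of the six overlap/gap statistics lies
within a relative `tolerance` of the reference value. Acceptance is pure
rejection from independent proposals — no Markov chain — so accepted
configurations are i.i.d. given the gate. The adjacency is held fixed
across samples; accepted configurations differ from the reference only
in geometry, and their efficiencies form the null distribution.

A reference statistic of exactly 0 (possible on overlap-free synthetic
references) has no relative scale; such statistics are compared against
an absolute threshold `zero_abs_tol` (default 0.05 mm). Internally the
recorded error for a zero-reference statistic is scaled so the uniform
rule "all six errors ≤ tolerance" is exactly the absolute test. If
nothing is accepted within `max_proposals` the (empty) ensemble is
returned with a classed warning suggesting tolerance relaxation, never a
silent empty result.

The strict 5% gate of tight real-data analyses needs very large proposal
budgets; desk-scale analyses in this package use `tolerance = 0.25`,
which on 10–23-region instances accepts at rates around $10^{-4}$ to
$10^{-2}$ and reproduces the qualitative picture (the efficiency-wired
configuration sits in the null's upper tail).

## Locating an observation

`percentile_of()` uses strict-less-than counting (ties count above;
`ties = "midrank"` gives ties half weight), and `zscore_of()` uses the
sample ($n-1$) standard deviation; both conventions are stated because
different choices move results at the margin. `compare_ensembles()`
reports the observation's percentile and z-score on the optimized and
random ensembles, its distance from the optimized median in
optimized-sd units, and histogram tables on shared Freedman–Diaconis
bins (computed on the union of both ensembles so overlays align), with
full settings/seed provenance echoed for reproducibility.

## Graph diagnostics

`binarize()` turns the weighted adjacency into a directed 0/1 graph (any
positive projection volume is an edge by default; the threshold is
configurable). `global_efficiency()` is the mean inverse shortest-path
length over ordered pairs ($1/\infty = 0$). `clustering_coefficient()`
averages local clustering over all nodes of the symmetrized graph, with
degree-<2 nodes contributing 0. `small_world_index()` reports
$\sigma = (C/C_{\mathrm{rand}})/(L/L_{\mathrm{rand}})$ against
degree-preserving rewired nulls (double-edge swaps, $10|E|$ swaps per
sample, 100 samples by default); a disconnected symmetrized graph yields
an explicit `sigma = NA` report instead of an error. Shortest paths,
rewiring and clustering are delegated to igraph; the test suite checks
them against independent breadth-first-search and triangle-counting
oracles.

## The synthetic generator

`generate_regions()` draws log-normal volumes (defaults
`meanlog = log(0.4)`, `sdlog = 0.8`, i.e. mostly 0.1–2 mm³ — the scale
of small brain sub-regions) and places spheres by sequential random
insertion into a cubic sub-box sized so the spheres fill
`packing_fraction = 0.35` of it, accepting a placement only when every
overlap with already-placed spheres is at most `overlap_cap_mm = 0.8`.
Larger spheres are placed first; each sphere has a retry budget of
$10^4$. This emulates the features the analysis relies on — a tight
cluster a few mm across inside a 15 mm working box, a minority of
region pairs overlapping slightly (mean overlap on the 0.2 mm scale,
capped at 0.8 mm), heavy-tailed volumes — while remaining deterministic
from its seed. It does **not** emulate non-spherical region geometry,
anatomically structured (non-random) adjacency of real regions, or
laterality; passing tests on synthetic instances therefore validate the
pipeline's mechanics and statistical behavior, not anatomical claims.

`generate_adjacency()` wires each ordered pair with probability
`edge_density` (default 0.35) and log-normal weights (defaults
`meanlog = log(0.005)`, `sdlog = 1.2` mm³, the scale of tracing
projection volumes). With `distance_decay_lambda` set, both edge
probability and weight are damped by $e^{-d/\lambda}$;
`generate_ground_truth_efficient()` requires the decay and records
$\lambda$, producing instances whose strong projections span short
distances — by construction their efficiency sits in the upper tail of
geometry-matched random repackings, the property the end-to-end tests
check (and recover in at least 8 of 10 generator seeds at $n = 10$,
tolerance 0.25, 500-sample ensembles).

Sequential insertion was chosen over force relaxation because it is
deterministic, fast and sufficient for the target overlap statistics; a
relaxation step would allow higher packing fractions but add an
iteration-order dependence.

## Problem sizes and reproducibility

The shipped analyses use desk-scale sizes chosen to make every result
reproducible in minutes on a single core: restart ensembles of 10–30
(two-digit ensembles already expose the landscape's multi-modality),
rejection ensembles of 100–500 accepted configurations at tolerance
0.25, and oracle sweeps over 100 random instances of up to 12 regions.
`scripts/acceptance.R` runs the full pipeline — generation, both
optimized ensembles, bulk reduction, the random ensemble, comparison,
and graph diagnostics — from a single master seed; every stage derives
its sub-seed by a fixed offset, so identical seeds give identical
numbers. All package randomness flows through isolated RNG streams that
never disturb the caller's `.Random.seed`.

## Known limitations

- Spheres are a crude proxy for real region shapes; distances between
  centers can over- or under-state axonal path lengths.
- The optimizer is local: the restart ensemble characterizes the
  landscape but certifies no global optimum.
- Rejection sampling becomes expensive as the tolerance tightens or the
  region count grows; the strict 5% gate at 23 regions is beyond
  desk-scale budgets.
- The uniform overlap cap treats all pairs alike; per-pair caps taken
  from an observed packing would need that packing as input.
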