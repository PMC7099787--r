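---
title: "Quadtree sampling frames: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadtree sampling frames: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadframe)
```

# The problem

A household survey needs primary sampling units (PSUs) of roughly equal
population: selection probabilities and hence design weights derive from
unit populations, and wildly unequal units translate into wildly unequal
weights and inflated estimator variance. Where census enumeration areas are
unavailable, a gridded population surface can supply the frame, but its
natural units — fixed-size grid cells — are uniform in *area*, not in
*population*. This package constructs frames whose units are approximately
uniform in population instead, by recursive quadtree splitting of the
surface, and implements the surrounding multi-stage design: stratification,
allocation, PPS selection, household selection and weights.

# Smoothing

Modelled population surfaces often concentrate a settlement's population in
a few very high cells. Before framing, `gaussianSmooth()` spreads each
cell's count with an isotropic Gaussian kernel; the default standard
deviation is **500 m**, the value used in the Somali design this package
follows, expressed in metres and converted internally to cells as
`sigmaM / cellSize`.

Numerical conventions:

* The kernel is **truncated at 4σ** and applied separably (two 1-D band
  convolutions, implemented as dense band-matrix products).
* **Edges and masks.** The kernel mass a source cell would place on
  off-grid or masked-out cells is redistributed by renormalising *that
  cell's* kernel over valid cells. Writing `C` for the symmetric truncated
  convolution and `m` for the 0/1 mask, the output is
  `out = m ⊙ C(v / C(m))`: each source cell `i` distributes
  `v_i k_ij / W_i` with `W_i = Σ_{j valid} k_ij`. Masked-out cells receive
  nothing, and the masked-in total is conserved identically; a final scalar
  renormalisation absorbs floating-point residue, keeping the relative
  error far below the 1e-6 contract for any mask.
* Smoothed values stay **fractional** — unit populations are reported from
  the smoothed surface without rounding.
* A `sigmaM` below half a cell cannot be resolved on the grid; the input is
  returned unchanged with a warning.

Two consequences of the edge rule are worth knowing. First, a constant
field is reproduced exactly only at cells more than **two** truncation
radii from a mask or grid edge: edge cells renormalise their kernels, and
those kernels reach one radius inward. Second, for the same reason the
maximum cell value can *rise* slightly near mask boundaries (pushed-back
mass); the never-increasing-maximum property holds whenever the populated
support sits at least a truncation radius inside the grid, and the tests
check it there. Conservation was judged more important than strict
max-monotonicity at edges, since frame populations are sums, not maxima.

# Quadtree decomposition

`quadtreePartition()` recursively splits squares into four quadrants until
each leaf satisfies **population < `popMax`** (default 3500 persons) *and*
**side ≤ `sideMaxM`** (default 3000 m); the area cap keeps enumeration
areas walkable for field teams even in empty terrain.

Design choices, all deterministic:

* **Root sizing.** Quadrant halving only hits the 30-cell (3 km at 100 m)
  area cap exactly if the root side is `sideMaxCells · 2^m`. We therefore
  pad the grid (zero population, masked out, grid at the root's top-left)
  to the smallest such square covering it. When `sideMaxCells` exceeds the
  grid's larger dimension the area rule can never bind, and the root is
  simply the smallest power of two covering the grid — this keeps leaves
  aligned to the natural quadrants of small grids instead of an arbitrary
  over-sized anchor.
* **Odd sides** split at `floor(s/2)`, so quadrants are equal up to one
  cell and leaves are square up to one cell of floor/ceil asymmetry
  (`side_m` reports the larger dimension).
* **Emission order** is depth-first NW, NE, SW, SE; unit ids encode the
  cell offsets and size (`q<row>_<col>_<h>x<w>`), so identical inputs give
  identical frames.
* **Mask handling.** Leaves wholly outside the valid mask are dropped;
  leaves straddling the mask edge are kept whole with population summed
  over valid cells only. Zero-population leaves inside the mask are
  retained — empty units are legitimate frame members with selection
  probability 0.
* **Unsplittable cells.** A single cell at or above `popMax` is emitted
  with `flag_overflow = TRUE` rather than erroring; whenever no input cell
  reaches `popMax`, every leaf is strictly below it (the splitting rule
  guarantees this, and the acceptance suite verifies it).
* Splitting decisions use the **same surface** that populates the output
  (i.e. the smoothed values), so the constraint tested is the constraint
  reported.

Block sums use an integral image, making each node O(1); the whole
decomposition of a 512 × 512 grid runs in well under a second.

# Baseline frames and homogeneity diagnostics

`ugcPartition()` tiles the grid with fixed squares anchored at the grid
origin, retaining partial edge tiles and dropping tiles with no masked-in
cell — the conventional uniform-grid-cell (UGC) frame. `frameMetrics()`
reports, nationally and per admin region, the unit count, min, max, mean,
standard deviation and coefficient of variation of unit populations.
Fixed conventions: the std uses the population (`ddof = 0`) denominator
(immaterial at realistic unit counts, but it must be pinned for tests); cv
is the ratio `std/mean`, reported only when the mean is positive; units are
assigned to regions by centroid, with boundary ties going to the lowest
region id.

# Stratification and allocation

`stratify()` crosses admin regions with population types. Membership is
hierarchical at any evaluation point: IDP camp polygons win over urban
boundaries, which win over the rural remainder — so strata are disjoint and
exhaustive within each region *by construction*. Because no polygon-algebra
library is assumed, strata are stored as composite geometries (region plus
urban/IDP include/exclude sets) evaluated by the **cell-centre rule**, the
same rule used to assign raster cells to polygons everywhere in the
package; at raster resolution this is exactly equivalent to materialised
intersections. Admin overlap detection uses the grid's cell centres when a
grid is supplied, otherwise a probe lattice (exact for rectangular test
geometries, approximate in general).

`neymanAllocate()` implements optimal allocation
`n_h = n · N_h S_h / Σ_h N_h S_h`, with `S_h` the within-stratum standard
deviation of the survey variable (an input, typically estimated from a
prior survey wave). Conventions: fractional allocations are integerised by
**largest remainder** with ties broken by stratum order; the minimum of
**2 PSUs per stratum** (needed for stratum-level variance estimation) is
enforced by lifting deficient strata to the floor and re-allocating the
excess proportionally among the rest, iterating until stable; deliberate
oversampling is expressed as exact per-stratum overrides rather than
hard-coded city lists. The allocation is invariant to rescaling all `S_h`,
and `Σ n_h = n` always.

# PSU selection and household selection

`ppsSystematic()` draws `k` PSUs **with replacement** by systematic PPS:
units are cumulated in the frame's deterministic emission order, the
interval is `I = total/k`, one uniform start `u ∈ [0, I)` is drawn, and
hits `u + jI` are mapped through the cumulative totals. Units larger than
`I` are selected with certainty, possibly more than once; multiplicities
always sum to `k`. Zero-population units are excluded from the cumulation
(probability 0). The frame order is recorded in provenance, so any draw is
replayable; a `randomStart` override supports audits and worked examples.

`replacementSample()` draws the replacement list — default **20%** of `k`,
rounded up — by an independent systematic pass under a seed derived from
the main seed through a documented Lehmer step (`(seed·48271 + stream) mod
2^31−1`, exact in doubles); every record carries its seed. A substituted
replacement inherits the original PSU's selection probability in the weight
calculation, the convention under which no-population replacements do not
bias estimates.

`selectHousehold()` implements the in-PSU tablet protocol: one structure
uniformly at random per secondary sampling unit (SSU), then one household
uniformly within the structure, giving a household probability of
`1/(n_structures × n_households_in_its_structure)`. Empty SSUs are flagged
for replacement, not errors.

# Weights

First-stage probability: `P1 = k · n_hi / N_h` for a PSU of population
`n_hi` in a stratum of `N_h` — an expected-hit rate that can exceed 1 for
certainty units. Inside `householdWeight()` it is **capped at 1** (a
certainty unit's inclusion probability is 1) and the cap is flagged.

SSU plans (`ssuPlan()`) encode the segmentation protocol: 12 SSUs of ~12
structures in the standard case, with three special rules — PSUs under 12
structures are not segmented (1 SSU); PSUs over 150 structures get
`ceiling(n/12)` SSUs; and a PSU selected `t` times gets its SSU count
scaled by `t`. One household is interviewed per SSU, so
`P2 = 1/m` with `m = households_in_psu / n_ssu`, and the design weight is
`w = 1/(P1 · P2)`. Note the multiplicity scaling makes a multiply-hit PSU
contribute `households/P1` to a weighted total exactly once — the scaled
interview count and the shrunken `P2` cancel.

`weightDiagnostics()` reports the max/min weight ratio, the relvariance
`cv²(w) = n Σw²/(Σw)² − 1`, and the Kish unequal-weighting effect
`deff_w = 1 + cv²(w)` — the variance-inflation component attributable to
weight variation alone, which is the component frame homogeneity directly
controls. `deff_w ≥ 1` with equality iff all weights are equal. Other
weight-dispersion statistics sometimes quoted for survey comparisons lack a
standard definition and are deliberately not computed; full design-effect
estimation (intra-cluster correlation) is out of scope.

# The synthetic world

`syntheticSpec()` + `makePopulationRaster()` fabricate the input regime the
method targets: isotropic Gaussian settlement clusters (blob totals
renormalised inside the grid so the raster total is *exactly* the stated
sum, making conservation tests sharp) over a near-zero uniform background,
with rectangular admin regions, disk-shaped urban boundaries around each
cluster and one small IDP square. Defaults — 512 × 512 cells at 100 m
(~51 km square), 8–10 clusters of 5,000–50,000 people with 400–1500 m
spreads, background 0.02 persons/cell — were chosen once to mimic a
sparsely settled region with a handful of towns at the resolution of a
100 m population surface, and to run end-to-end in seconds; cluster
parameters keep every single cell below the 3500-person threshold, so the
split rule, not the overflow flag, is what the tests exercise.

What the generator does **not** emulate: covariate-driven (dasymetric)
population models, real boundary complexity, population displacement, or
any spatial autocorrelation beyond the Gaussian blobs. A green test suite
therefore establishes that the algorithms implement their definitions and
their invariants hold on this class of surfaces — not that any particular
national figure is reproduced, which would require the original raster and
the original code's undocumented anchoring and edge conventions.

# Degenerate inputs and tolerances

* Empty mask → empty frame; disjoint mask polygon → all-false mask with a
  warning, not an error.
* Negative raster values are rejected at load; nodata becomes 0 but stays
  tracked in the mask.
* Conservation contracts: smoothing ≤ 1e-6 relative (achieved ~1e-15);
  quadtree and UGC partitions exact up to float summation order (tested at
  1e-9 relative and stricter).
* All randomness flows from a single user seed through the recorded
  splitting scheme; reruns are byte-identical.

# Known limitations

* Raster I/O is plain-text ASCII grid only; binary GeoTIFFs must be
  converted/reprojected upstream.
* Strata are geometric predicates, not materialised polygons; exporting
  stratum *boundaries* (rather than stratum-tagged frames) is not
  supported.
* The admin-overlap check without a grid uses a probe lattice and can miss
  slivers smaller than its spacing.
* Nomadic populations, manual SSU delineation from imagery and visual PSU
  screening are field tasks outside this package; an exclusion list stands
  in for imagery screening.
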