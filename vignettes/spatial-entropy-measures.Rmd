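---
title: "Spatial entropy measures: models, conventions and design choices"
author: "spentropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial entropy measures: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spentropy)
```

## The problem

Ecologists and epidemiologists routinely summarise the heterogeneity of a
categorical spatial phenomenon — species occurrences, nest sites of an
animal population, land-cover classes, disease cases by type — with a
single diversity number. Shannon's entropy is the classical choice, but it
is blind to *where* the observations sit: rearranging the observations in
space leaves it unchanged. This package implements the family of entropy
measures that re-introduce space in three complementary ways — through an
area partition (Batty and its LISA variant), through co-occurrences of
category values at neighbouring or nearby locations (O'Neill, contagion,
Parresol–Edwards, Leibovici), and through an exact information-theoretic
decomposition of the pair entropy into a spatial and a residual part —
for two data types: marked point patterns in a polygonal observation
window, and categorical rasters with a NODATA mask.

All entropies are in nats (natural logarithms). Coordinates are planar and
projected (think UTM metres); all distances are Euclidean. Geodesic
coordinates, CRS handling and reprojection are out of scope.

## Measures

### Shannon

For a categorical variable $X$ with $I$ outcomes,
$H(X) = \sum_{i=1}^I p(x_i)\log\frac{1}{p(x_i)} \in [0, \log I]$, with the
plug-in estimate $p(x_i) = n_i/n$. We report the relative entropy
$H/\log I$ (defined as 1 when $I = 1$, where the maximum is attained
trivially). Zero-count categories contribute zero by the usual continuity
convention. Model-based probability estimates are deliberately excluded:
the package describes data, it does not predict.

### Batty (partition-based)

Given a partition of the window into $G$ sub-areas with sizes $T_g$
($\sum_g T_g = |T|$) and observation probabilities $p_g = n_g/n$, the
intensity is $\lambda_g = p_g/T_g$ and
$$H_B = \sum_{g=1}^G p_g \log\frac{1}{\lambda_g} \in [\log T_{g^*},\, \log|T|],$$
with $g^*$ the smallest sub-area. Sizes enter through logarithms, so they
carry units. The working unit defaults to the squared coordinate unit
(square metres for UTM data), with a `size_scale` multiplier to change it.
Two numerical rules matter:

* **Small-area rescaling.** If any $T_g \le 1$ in the working unit, the
  sizes are multiplied by the smallest power of ten $c$ with
  $\min_g T_g \cdot c > 1$, the entropy is computed, and $\log c$ is
  subtracted — an exact identity, applied automatically
  (`rescale = TRUE`).
* **Relative value.** We report $H_B / \log|T|$ — the normalisation that
  reproduces the published worked value (0.97) for the vegetation-based
  partition from its frequency table, unlike the range-anchored form
  $(H_B - \log T_{g^*})/(\log|T| - \log T_{g^*})$, which gives about
  0.71 on the same inputs. When the rescaling triggered, the relative
  value is computed on the rescaled scale, $(H_B + \log c)/\log(|T|c)$:
  this coincides with $H_B/\log|T|$ whenever $c = 1$ and stays defined
  for windows with $|T| \le 1$ working unit (e.g. unit-square synthetic
  windows). The reported range always refers to original units.

### Batty LISA (neighbourhood-smoothed)

The Karlström–Ceccato variant discards the sizes and replaces each $p_g$
inside the logarithm by an aggregate $\tilde p_g$ over the sub-area and
its `neigh` nearest sub-areas (Euclidean centroid distance, ties broken by
the lower sub-area id; `neigh` counts neighbours *beyond* self):
$H_{LISA} = \sum_g p_g \log(1/\tilde p_g)$, nominal range $[0, \log G]$.
The literature does not pin down whether $\tilde p_g$ is a sum or an
average, nor whether self is included, so both schemes are exposed:

* `"average"` (default, row-standardised weights including self): full
  smoothing (`neigh = G-1`) gives $\tilde p_g = 1/G$ and exactly
  $\log G$, matching the description of the index approaching its maximum
  as the neighbourhood grows.
* `"sum"`: provided for compatibility experiments; it provably respects
  $0 \le H \le \log G$.

Two honest caveats, found while validating the implementation and worth
knowing when interpreting results. First, $H_{LISA}$ is *not* a monotone
function of `neigh` instance-by-instance — smoothing raises the entropy in
the mean and at the endpoints ($H(G-1) = \log G \ge H(0)$ for the average
scheme), but individual configurations can dip. Second, under the
`"average"` scheme at intermediate `neigh` the value can slightly exceed
$\log G$ when occupied sub-areas have nearly-empty neighbours, so the
relative value can marginally exceed 1 there; the nominal range is
reported regardless, as is conventional.

### Co-occurrence entropies

With $I$ base categories, the couple variable $Z$ has $I^2$ ordered
outcomes. O'Neill's entropy is the Shannon entropy of the couple
distribution over all rook-adjacent cell pairs of a grid, range
$[0, \log I^2]$; the relative contagion index is $1 - H_O^{rel}$ and
Parresol–Edwards' entropy is $-H_O$. Leibovici's entropy replaces
contiguity by "within distance $d$" (inclusive, so that $d =$ cell size
recovers exactly the rook pair multiset on square grids) and therefore
extends to point data.

Enumeration conventions are where reproducibility lives:

* **Contiguity**: each adjacency is visited once by scanning every valid
  cell's east and south neighbour; the ordered couple is (scan origin,
  neighbour). Pairs touching NODATA cells do not exist.
* **Distance couples**: each unordered pair within $d$ is visited once,
  iterating over the canonical order (ascending x, then y, then input
  order) and recording the ordered couple (earlier, later). The published
  point-data table shows unequal mixed counts (3780 vs 3835), which is
  impossible under symmetric double counting — the counts evidently come
  from a single pass in some internal order. The canonical order makes our
  single pass deterministic; a `symmetrise` flag splits mixed counts
  equally when a direction-free table is wanted.
* Grid distances are centroid-to-centroid in physical units
  (`xstep`/`ystep`), so rectangular cells are handled transparently.
* The internal enumeration is blocked to bound memory, but its output is
  defined — and tested — to equal the brute-force $O(n^2)$ definition
  exactly.

Co-occurrence sets of more than two observations and queen contiguity are
out of scope.

### Decomposable entropy

The decomposable (spatial mutual information) entropy replaces ordered
couples by unordered pairs ($I(I+1)/2$ outcomes, category pair sorted), on
the grounds that co-occurrences have no direction in space, and classifies
*every* pair of observations (no distance cutoff) into distance classes
$w_k = (b_{k-1}, b_k]$. With $p(w_k)$ the share of pairs in class $k$:
$$H(Z) = MI(Z,W) + H(Z)_W
 = \sum_k p(w_k)\left[PI(Z|w_k) + H(Z|w_k)\right],$$
where $PI(Z|w_k)$ is the Kullback–Leibler divergence of the within-class
pair distribution from the global one (hence $\ge 0$, as is $MI$), and
$H(Z|w_k)$ the within-class Shannon entropy. The identity holds exactly
by construction and is asserted to $10^{-9}$ on every input in the test
suite. `decomposition_profile()` exports the per-class spatial share
$PI/(PI+H)$ (0 when both terms vanish) behind the standard stacked bar
plot; plotting itself is left to the user (only data export is provided).

Default distance classes follow standard spatial-statistics practice: on
square-cell grids, breaks $(0, c], (c, 2c], (2c, \infty)$ — the 4 rook
neighbours, then the next 12 cells (diagonals at $c\sqrt2$, second-order
axials at $2c$), then the residual; the rule refuses rectangular cells,
where these rings are not well defined. For point data, the type-7
deciles (10%–90%) of the nearest-neighbour distances, deduplicated,
starting at 0, plus the residual class. Two edge rules are fixed
deliberately: a pair at exactly a break belongs to the lower class, and
coincident observations (distance 0) are counted in the first class even
though the classes formally partition $(0,\infty)$ — dropping real
observations would be worse than bending the formalism. Empty classes are
dropped from the weighted sums with a warning (their weight is zero
anyway).

Note that with the NN-decile default on weakly structured point data the
finite classes hold a tiny fraction of all pairs (most pairwise distances
far exceed NN distances), so their estimated spatial shares are noisy;
when class-level shares matter, pass breaks at pairwise-distance
quantiles instead to balance the classes.

## Data model and I/O conventions

* **Windows** are simple polygons; the area is the shoelace formula,
  orientation-free; points on the boundary count as inside, so border
  observations are never silently lost.
* **Rasters** store row 1 as the southernmost row; cells are half-open
  $[x_{lo}, x_{hi}) \times [y_{lo}, y_{hi})$, so a point on a shared edge
  deterministically belongs to the higher-index cell; the centroid of cell
  $(r, c)$ is $(x_0 + (c-\tfrac12)\,dx,\; y_0 + (r-\tfrac12)\,dy)$.
  `NA` marks NODATA; padding a raster with extra NODATA rows changes no
  statistic (tested).
* **Pixellation** of a point pattern is binary: a cell is `"1"` if at
  least one point falls in it (multiplicity collapses), `"0"` otherwise;
  cells whose centroid falls outside the window polygon are masked.
* **Formats**: points as CSV with `x`, `y` and optional mark columns;
  windows as WKT `POLYGON` or GeoJSON `Polygon`; rasters as ESRI ASCII
  grids, where a documented extension replaces the `cellsize` header line
  by `dx` and `dy` lines for rectangular cells (the reader accepts both
  dialects; the writer emits the extension only when needed); partitions
  as GeoJSON FeatureCollections with an `id` property, or as categorical
  rasters. Quantile classes of continuous covariates use type-7
  (linear-interpolation) quantiles with left-open/right-closed intervals,
  the lowest closed — a fixed documented choice where references are
  silent.
* **Voronoi partitions** draw generators uniformly in the polygon by
  seeded rejection sampling, tessellate with `deldir`, and clip each tile
  to the window with polygon clipping, so sub-area sizes sum to the
  window area (to $10^{-6}$ relative, tested, and cross-checked against
  an independent tessellation implementation). Points are assigned to the
  nearest generator, ties to the lower id. Generators closer than
  $10^{-8}$ of the window extent are resampled with a message.

## The synthetic generators, and what passing tests show

The package has no bundled field dataset; generators stand in for it, and
each is a pure function of its configuration plus a seed (base R
Mersenne-Twister; study functions derive per-replicate sub-seeds from the
master seed once, via `sample.int`, so runs are reproducible and
independent of replicate order).

* `generate_csr()` — homogeneous Poisson-like uniform locations,
  optionally with independent marks: the null model. Its mean
  nearest-neighbour distance matches the closed form
  $0.5/\sqrt{n/|T|}$ within 10% at $n = 2000$ (edge effects account for
  the slack).
* `generate_clustered()` — a Thomas-like process (uniform parents,
  Poisson offspring counts, isotropic Gaussian displacement, clipped to
  the window). With parent-inherited marks it plants genuine short-range
  mark association, which the decomposition detects as MI well above the
  CSR null.
* `generate_autocorrelated_raster()` — Gaussian noise, optionally
  smoothed with a Gaussian kernel (SD in cells, edge-renormalised),
  thresholded at the $(1-p_1)$ quantile: marginal frequency
  $\approx p_1$, clumping grows with the smoothing radius. At zero
  smoothing the contagion matches the independent-cells closed form
  $p_{ab} = p_a p_b$.

These emulate the *mechanisms* the measures respond to — uniformity,
clustering, mark inheritance, autocorrelation — not the particulars of
real ecological data: no inhomogeneous intensity driven by covariates, no
anisotropy, no irregular masks interacting with clustering. Passing tests
therefore certify the computations and their stated invariants, not that
any ecological conclusion transfers.

The two sensitivity studies mirror the published designs at sizes chosen
for desk-scale runs. `resolution_sensitivity()` pixellates one pattern
over grids from $10\times10$ to $500\times500$ and traces the modifiable
areal unit problem: the occupied fraction collapses, every presence-based
relative entropy (Shannon and the couple-based family) decays towards 0,
and contagion rises towards 1 — a zero here reflects the discretisation,
not an absence of the phenomenon, which is exactly why the grid
resolution must be chosen (we echo the recommendation to match the
covariate resolution, and to prefer point data when available). The test
suite runs this on a 647-point CSR fixture. `random_partition_study()`
repeats seeded Voronoi partitions per $G$ and summarises relative Batty
and LISA entropies by mean and empirical percentile intervals; the suite
uses tens of replicates per $G$ (the published study used 1000 — the
design is identical, only `reps` differs) and checks that CSR yields
near-maximal relative Batty entropy, robust to $G$. The acceptance
checks for the decomposition null use 20 replicates of 500 marked CSR
points (about 125,000 pairs each), giving mean MI below 0.01 nats.

## Known limitations

* All-pairs routines (`altieri_decomposition`, large-distance
  `distance_couples`) materialise $n(n-1)/2$ distances; fine up to a few
  thousand observations, not for $10^5$-cell rasters. The enumeration is
  blocked for memory, not for time.
* Batty-type measures need every point covered by a sub-area; partitions
  from a raster covering less than the window will error on uncovered
  points rather than guess.
* Neighbourhood systems from shared polygon borders (adjacency graphs)
  are not implemented; LISA neighbourhoods are k-nearest-centroid only.
* GeoJSON/WKT support covers single exterior rings; polygons with holes
  are rejected.
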