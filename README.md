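# spentropy

Spatial entropy measures for marked point patterns and categorical
rasters.

Classical diversity summaries such as Shannon's entropy ignore *where*
observations sit: shuffle the locations and the index does not move. For
spatially arranged categorical data — nest sites of an animal population,
land-cover classes on a grid, disease cases by type — ecologists and
spatial statisticians therefore use a family of entropies that
re-introduce space. `spentropy` implements that family end to end, for
two data types: point patterns with categorical marks inside a polygonal
observation window, and categorical rasters with a NODATA mask.

## The measures

With natural logarithms throughout (all values in nats):

* **Shannon**: `H(X) = Σ_i p(x_i) log(1/p(x_i))`, range `[0, log I]`,
  with plug-in frequencies `p(x_i) = n_i/n`; relative value `H/log I`.
* **Batty** (partition-based): for a partition into `G` sub-areas with
  sizes `T_g` and point shares `p_g`, intensity `λ_g = p_g/T_g` and
  `H_B = Σ_g p_g log(1/λ_g)`, range `[log T_g*, log |T|]`; sub-areas
  smaller than 1 working unit trigger an automatic power-of-ten rescale
  with exact `log c` correction. Relative value `H_B / log |T|`.
* **Batty LISA** (Karlström–Ceccato): sizes replaced by smoothed
  probabilities over each sub-area's `neigh` nearest sub-areas (average
  or sum scheme), `H = Σ_g p_g log(1/p̃_g)`, nominal range `[0, log G]`.
* **O'Neill / contagion / Parresol–Edwards**: Shannon entropy of the
  ordered-couple variable `Z` over rook-adjacent grid cells, range
  `[0, log I²]`; relative contagion is `1 − H_O^rel`; Parresol–Edwards
  is `−H_O`.
* **Leibovici**: the same couple entropy with contiguity generalised to
  "within distance d" (inclusive), applicable to point data.
* **Decomposable entropy**: unordered pairs at *all* distances,
  partitioned into distance classes `w_k`, with the exact decomposition
  `H(Z) = MI(Z,W) + H(Z)_W` splitting the pair entropy into spatial
  mutual information and residual entropy, plus per-class partial terms.

Around the measures the package provides the machinery a study needs:
window/point/raster I/O (CSV, WKT/GeoJSON polygons, ESRI ASCII grids with
a rectangular-cell header extension), binary pixellation of point
patterns, partition builders (seeded random Voronoi tessellations,
covariate quantile classes, raster categories, user GeoJSON), distance
summaries, seeded synthetic generators (CSR, Thomas-like clusters,
autocorrelated rasters), the grid-resolution and random-partition
sensitivity studies, and a command-line interface.

## A worked example

```r
library(spentropy)

# Shannon entropy of a two-category mark frequency table
shannon_entropy(category_distribution(c(major = 350, minor = 297)))
#> Shannon entropy: 0.69 nats, range [0.00, 0.69], relative 1.00

# Batty's entropy from per-sub-area frequencies and sizes (m^2)
batty_from_components(c(89, 20, 517, 21),
                      c(8.72, 4.18, 6.29, 6.43) * 1e6,
                      total_area = 19.874e6,
                      ids = c("Disturbed", "Grassland", "Primary", "Secondary"))
#> Batty entropy: 16.36 nats, range [15.25, 16.80], relative 0.97

# O'Neill's contiguity entropy from an ordered-couple count table
oneill_entropy(cooccurrence_table(c(39775, 919, 919, 179),
                                  categories = c("0", "1")))
#> O'Neill entropy: 0.24 nats, range [0.00, 1.39], relative 0.17

# a synthetic marked pattern: 647 uniform points, independent binary marks
w   <- obs_window(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
pat <- generate_csr(w, 647, seed = 42, mark_probs = c(major = .54, minor = .46))
leibovici_entropy(pat, d = 50)
#> Leibovici entropy: 1.37 nats, range [0.00, 1.39], relative 0.99
dec <- altieri_decomposition(pat)
sprintf("H(Z) = %.4f, MI = %.6f, residual = %.4f", dec$H_Z, dec$MI, dec$residual)
#> "H(Z) = 1.0317, MI = 0.000042, residual = 1.0317"
```

Reading the output: the mark frequencies are near-even, so mark diversity
sits at its maximum (relative 1.00) — but Shannon says nothing spatial.
The Batty value 0.97 says the per-area intensity of the phenomenon is
nearly flat across the four sub-areas. The O'Neill value 0.17 (relative
contagion 0.83) says adjacent grid cells overwhelmingly form homogeneous
couples, driven by the dominant background category. For the random
pattern, couples within 50 units are near-uniform across the four mark
combinations (relative 0.99) and the mutual information is essentially
zero: space explains nothing about the marks, exactly as built.

The command-line interface exposes the same operations
(`shannon`, `batty`, `batty-lisa`, `oneill`, `contagion`, `parredw`,
`leibovici`, `altieri`, `simulate`, `sensitivity`, `partition-study`):

```sh
Rscript <library>/spentropy/exec/spentropy leibovici \
    --points pts.csv --window win.wkt --mark group --distance 500 --out run1
```

writes `result.json`, `table.csv`, the resolved `config.json` and a
`run.log` into `run1/`.

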