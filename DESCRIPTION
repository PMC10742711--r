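Package: spentropy
Title: Spatial Entropy Measures for Point Patterns and Categorical Rasters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the main families of spatial entropy and diversity
    measures for marked point patterns in polygonal observation windows and
    for categorical rasters: Shannon's entropy with relative frequencies,
    Batty's partition-based entropy with automatic rescaling for small
    sub-areas, its neighbourhood-smoothed LISA variant, O'Neill's
    contiguity entropy with the relative contagion and Parresol-Edwards
    indices, Leibovici's distance-based co-occurrence entropy, and the
    decomposable entropy that splits Shannon's entropy of the pair variable
    into spatial mutual information and residual entropy over distance
    classes. Includes partition builders (random Voronoi tessellations,
    covariate quantile classes, raster categories), readers and writers for
    CSV point patterns, WKT/GeoJSON polygon windows and ESRI ASCII grids,
    seeded synthetic-pattern generators, grid-resolution and
    random-partition sensitivity studies, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    jsonlite,
    polyclip,
    sp,
    stats,
    utils
Suggests:
    spatstat.geom,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
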