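test_that("default distance classes follow the neighbour-ring rule on grids", {
  r <- spat_raster(matrix(c("a", "b", "a", "b"), 2, 2))
  expect_equal(default_breaks(r), c(0, 1, 2, Inf))
  r5 <- spat_raster(matrix("a", 3, 3), xstep = 5, ystep = 5)
  expect_equal(default_breaks(r5), c(0, 5, 10, Inf))
  rect <- spat_raster(matrix("a", 3, 3), xstep = 1, ystep = 2)
  expect_error(default_breaks(rect), "rectangular")
})

test_that("point default breaks are NN-distance deciles, deduplicated", {
  w <- obs_window(c(0, 10, 10, 0), c(0, 0, 10, 10))
  # unit-spacing lattice: all NN distances 1, deciles collapse to one break
  g <- expand.grid(x = 0:4, y = 0:4)
  lat <- point_pattern(g$x, g$y, w)
  expect_equal(default_breaks(lat), c(0, 1, Inf))
  # 2 points: single finite break at their distance
  p2 <- point_pattern(c(0, 3), c(0, 0), w)
  expect_equal(default_breaks(p2), c(0, 3, Inf))
  # generic pattern: finite breaks equal the type-7 NN deciles
  pat <- random_marked_pattern(40, seed = 91)
  nn <- distance_summaries(pat)$nn_distances
  expect_equal(default_breaks(pat),
               c(0, unique(quantile(nn, seq(.1, .9, .1), type = 7,
                                    names = FALSE)), Inf))
})

test_that("the 4-corner worked decomposition is reproduced exactly", {
  dec <- altieri_decomposition(four_corner_pattern(), breaks = c(0, 1, Inf))
  expect_equal(dec$H_Z, log(6) - (4 / 6) * log(4), tolerance = 1e-12)
  expect_equal(dec$MI, (4 / 6) * log(6 / 4) + (2 / 6) * log(3),
               tolerance = 1e-12)
  expect_equal(dec$residual, (2 / 6) * log(2), tolerance = 1e-12)
  expect_equal(dec$MI, 0.6365142, tolerance = 1e-6)
  expect_equal(dec$residual, 0.2310491, tolerance = 1e-6)
  cl <- dec$classes
  expect_equal(cl$pairs, c(4, 2))
  expect_equal(cl$PI, c(log(6 / 4), log(3)), tolerance = 1e-12)
  expect_equal(cl$H, c(0, log(2)), tolerance = 1e-12)
  # global unordered-pair table: a-a 1, a-b 4, b-b 1
  expect_equal(dec$global$count, c(1, 4, 1))
})

test_that("one all-distance class makes the decomposition trivial", {
  pat <- random_marked_pattern(30, seed = 92)
  dec <- altieri_decomposition(pat, breaks = c(0, Inf))
  expect_equal(dec$MI, 0, tolerance = 1e-12)
  expect_equal(dec$residual, dec$H_Z, tolerance = 1e-12)
})

test_that("H(Z) = MI + residual and non-negativity hold on random inputs", {
  for (seed in 93:97) {
    n <- 20 + seed
    pat <- random_marked_pattern(n, seed = seed)
    dec <- altieri_decomposition(pat)
    expect_equal(dec$H_Z, dec$MI + dec$residual, tolerance = 1e-9)
    expect_gte(dec$MI, -1e-12)
    expect_true(all(dec$classes$PI >= -1e-12))
    R <- length(dec$pair_labels)
    expect_true(all(dec$classes$H >= 0 & dec$classes$H <= log(R) + 1e-9))
    expect_equal(sum(dec$classes$weight), 1, tolerance = 1e-12)
  }
})

test_that("per-class tables match the brute-force enumeration oracle", {
  for (seed in 98:99) {
    pat <- random_marked_pattern(70, seed = seed)
    breaks <- c(0, 1.5, 4, Inf)
    dec <- altieri_decomposition(pat, breaks = breaks)
    oracle <- brute_force_decomposition(pat$x, pat$y, pat$marks, breaks)
    expect_equal(dec$H_Z, oracle$H_Z, tolerance = 1e-12)
    expect_equal(dec$MI, oracle$MI, tolerance = 1e-12)
    expect_equal(dec$residual, oracle$residual, tolerance = 1e-12)
    for (k in seq_len(nrow(dec$classes))) {
      expect_equal(dec$class_tables[[k]]$count,
                   unname(oracle$class_counts[k, dec$pair_labels]))
    }
  }
  # grid data route
  m <- matrix(sample(c("p", "q"), 36, replace = TRUE), 6, 6)
  m[c(2, 35)] <- NA
  r <- spat_raster(m, xstep = 2, ystep = 2)
  vc <- valid_cells(r)
  dec <- altieri_decomposition(r)
  oracle <- brute_force_decomposition(vc$x, vc$y, as.character(vc$value),
                                      dec$breaks)
  expect_equal(dec$MI, oracle$MI, tolerance = 1e-12)
  expect_equal(dec$residual, oracle$residual, tolerance = 1e-12)
})

test_that("merging adjacent distance classes never increases MI", {
  for (seed in 111:115) {
    pat <- random_marked_pattern(60, seed = seed)
    breaks <- c(0, 1, 2.5, 5, Inf)
    full <- altieri_decomposition(pat, breaks = breaks)
    for (drop in 2:4) {
      merged <- altieri_decomposition(pat, breaks = breaks[-drop])
      expect_lte(merged$MI, full$MI + 1e-12)
    }
  }
})

test_that("profiles report spatial shares with degenerate classes as 0/1", {
  dec <- altieri_decomposition(four_corner_pattern(), breaks = c(0, 1, Inf))
  prof <- decomposition_profile(dec)
  expect_equal(prof$spatial_share[1], 1)          # class 1: PI > 0, H = 0
  expect_equal(prof$spatial_share + prof$residual_share, rep(1, 2))
  # single category: both terms vanish, share defined as 0 spatial
  w <- obs_window(c(0, 10, 10, 0), c(0, 0, 10, 10))
  p1 <- point_pattern(c(1, 2, 3), c(1, 1, 1), w, marks = rep("s", 3))
  d1 <- altieri_decomposition(p1, breaks = c(0, 1.5, Inf))
  expect_equal(d1$H_Z, 0)
  expect_true(all(decomposition_profile(d1)$spatial_share == 0))
})

test_that("marked-CSR patterns show near-zero spatial shares", {
  w <- unit_square()
  pat <- generate_csr(w, 300, seed = 117, mark_probs = c(a = .5, b = .5))
  # balanced classes (pairwise-distance deciles) so each share is well
  # estimated; the NN-decile default packs <0.1% of pairs into the short
  # classes, whose shares are then sampling noise
  br <- c(0, unique(distance_summaries(pat)$pairwise_quantiles[2:10]), Inf)
  dec <- altieri_decomposition(pat, breaks = br)
  prof <- decomposition_profile(dec)
  expect_lt(max(prof$spatial_share), 0.01)
  expect_lt(dec$MI, 0.01)
})
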