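test_that("contiguous couples enumerate each rook adjacency exactly once", {
  r12 <- spat_raster(matrix(c("0", "1"), 1, 2))
  t12 <- contiguous_couples(r12)
  expect_equal(t12$total_pairs, 1)
  expect_equal(t12$counts["0", "1"], 1)

  cb <- spat_raster(matrix(c("0", "1", "1", "0"), 2, 2))
  tcb <- contiguous_couples(cb)
  expect_equal(tcb$total_pairs, 4)
  expect_equal(unname(tcb$counts["0", "1"]), 2)
  expect_equal(unname(tcb$counts["1", "0"]), 2)

  # adjacency through NODATA never exists
  gap <- spat_raster(matrix(c("a", NA, "a"), 1, 3))
  expect_error(contiguous_couples(gap), "no adjacencies")
  # full m x n grid has m(n-1) + n(m-1) adjacencies
  full <- spat_raster(matrix("z", 4, 7))
  expect_equal(contiguous_couples(full)$total_pairs, 4 * 6 + 7 * 3)
})

test_that("O'Neill, contagion and Parresol-Edwards obey their identities", {
  set.seed(51)
  for (rep in 1:10) {
    counts <- matrix(rpois(4, 40) + 1, 2)
    tab <- cooccurrence_table(counts, categories = c("0", "1"))
    o <- oneill_entropy(tab)
    ct <- contagion(tab)
    pe <- parresol_edwards(tab)
    expect_equal(ct$value + o$relative, 1, tolerance = 1e-15)
    expect_equal(pe$value, -o$value, tolerance = 1e-15)
    expect_equal(pe$relative, o$relative, tolerance = 1e-15)
    expect_gte(o$value, 0)
    expect_lte(o$value, log(4) + 1e-12)
  }
  # degenerate extremes
  single <- cooccurrence_table(c(10, 0, 0, 0), categories = c("0", "1"))
  expect_equal(oneill_entropy(single)$value, 0)
  expect_equal(contagion(single)$value, 1)
  uni <- cooccurrence_table(rep(7, 4), categories = c("0", "1"))
  expect_equal(oneill_entropy(uni)$relative, 1, tolerance = 1e-12)
  expect_equal(contagion(uni)$value, 0, tolerance = 1e-12)
  expect_equal(parresol_edwards(uni)$value, -log(4), tolerance = 1e-12)
})

test_that("distance summaries give exact NN and pairwise distances", {
  w <- obs_window(c(0, 10, 10, 0), c(0, 0, 10, 10))
  p2 <- point_pattern(c(0, 3), c(0, 0), w)
  s2 <- distance_summaries(p2)
  expect_equal(s2$nn_distances, c(3, 3))
  expect_equal(s2$pairwise_distances, 3)

  p3 <- point_pattern(c(0, 1, 3), c(0, 0, 0), w)
  s3 <- distance_summaries(p3)
  expect_equal(s3$nn_distances, c(1, 1, 2))
  expect_equal(sort(s3$pairwise_distances), c(1, 2, 3))
  expect_error(distance_summaries(point_pattern(1, 1, w)), "at least 2")
})

test_that("distance couples follow the canonical pair enumeration", {
  w <- obs_window(c(0, 10, 10, 0), c(0, 0, 10, 10))
  p3 <- point_pattern(c(0, 1, 2), c(0, 0, 0), w, marks = c("a", "b", "b"))
  tab <- distance_couples(p3, d = 2.5)
  expect_equal(tab$total_pairs, 3)
  expect_equal(unname(tab$counts["a", "b"]), 2)
  expect_equal(unname(tab$counts["b", "b"]), 1)

  expect_error(distance_couples(p3, d = 0.5), "minimum interpoint")
  expect_error(distance_couples(p3, d = -1), "positive")
})

test_that("blocked pair enumeration equals the brute-force oracle", {
  for (cfg in list(list(n = 60, d = 2.2, seed = 101, labs = c("u", "v")),
                   list(n = 150, d = 1.4, seed = 102, labs = c("u", "v", "z")),
                   list(n = 200, d = 4.0, seed = 103, labs = c("u", "v")))) {
    set.seed(cfg$seed)
    x <- runif(cfg$n, 0, 10); y <- runif(cfg$n, 0, 10)
    mk <- sample(cfg$labs, cfg$n, replace = TRUE)
    w <- obs_window(c(0, 10, 10, 0), c(0, 0, 10, 10))
    pat <- point_pattern(x, y, w, marks = mk)
    got <- distance_couples(pat, cfg$d)
    want <- brute_force_couples(x, y, mk, cfg$d, labs = got$categories)
    expect_identical(unname(got$counts), unname(want))
    expect_equal(got$total_pairs, sum(want))
  }
  # raster route through valid-cell centroids, physical units
  m <- matrix(sample(c("p", "q"), 30, replace = TRUE), 5, 6)
  m[c(3, 17)] <- NA
  r <- spat_raster(m, xstep = 2, ystep = 2)
  vc <- valid_cells(r)
  got <- distance_couples(r, 4.1)
  want <- brute_force_couples(vc$x, vc$y, as.character(vc$value), 4.1,
                              labs = got$categories)
  expect_identical(unname(got$counts), unname(want))
})

test_that("couples at d = cell size match contiguity on square grids", {
  set.seed(61)
  m <- matrix(sample(c("a", "b", "c"), 120, replace = TRUE), 10, 12)
  m[sample(120, 20)] <- NA
  r <- spat_raster(m, xstep = 3, ystep = 3)
  tc <- contiguous_couples(r)
  td <- distance_couples(r, d = 3)
  expect_equal(td$total_pairs, tc$total_pairs)
  # same unordered pair multiset (orientations may differ)
  expect_equal(td$counts + t(td$counts), tc$counts + t(tc$counts))
})

test_that("symmetrising preserves totals and balances mixed couples", {
  counts <- matrix(c(10, 7, 2, 30), 2, byrow = TRUE)
  tab <- cooccurrence_table(counts, categories = c("a", "b"))
  s <- symmetrise_table(tab)
  expect_equal(s$total_pairs, tab$total_pairs)
  expect_equal(sum(s$probs), 1)
  expect_equal(unname(s$counts["a", "b"]), unname(s$counts["b", "a"]))
  expect_equal(unname(s$counts["a", "a"]), 10)
})

test_that("Leibovici entropy is bounded and degenerate for one category", {
  w <- obs_window(c(0, 10, 10, 0), c(0, 0, 10, 10))
  set.seed(71)
  pat <- point_pattern(runif(50, 0, 10), runif(50, 0, 10), w,
                       marks = rep("only", 50))
  res <- leibovici_entropy(pat, 5)
  expect_equal(res$value, 0)
  set.seed(72)
  pm <- point_pattern(runif(80, 0, 10), runif(80, 0, 10), w,
                      marks = sample(c("x", "y"), 80, replace = TRUE))
  r <- leibovici_entropy(pm, 3)
  expect_gte(r$value, 0)
  expect_lte(r$value, log(4) + 1e-12)
})

test_that("distance sweeps report each distance and flag empty ones", {
  w <- obs_window(c(0, 10, 10, 0), c(0, 0, 10, 10))
  pat <- random_marked_pattern(60, seed = 81, labs = c("u", "v"))
  sw <- distance_sweep(pat, c(0.01, 2, 5))
  expect_equal(nrow(sw), 3)
  expect_true(is.na(sw$relative[1]))  # below the minimum interpoint distance
  expect_equal(sw$relative[2], leibovici_entropy(pat, 2)$relative)
  # marked CSR: couples near-uniform, relative entropy near 1
  expect_true(all(sw$relative[2:3] > 0.95))
})
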