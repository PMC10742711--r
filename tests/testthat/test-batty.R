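test_that("Batty entropy reproduces hand-derived cases", {
  # all points in one of two sub-areas of size 2: single term 1 * log(2)
  b <- batty_from_components(c(5, 0), c(2, 2), total_area = 4)
  expect_equal(b$value, log(2), tolerance = 1e-12)

  # p_g proportional to T_g makes the intensity flat: maximum log|T|
  bm <- batty_from_components(c(25, 75), c(25, 75), total_area = 100)
  expect_equal(bm$value, log(100), tolerance = 1e-12)
  expect_equal(bm$relative, 1, tolerance = 1e-12)
})

test_that("Batty bounds hold when all sub-areas are occupied", {
  set.seed(31)
  for (rep in 1:20) {
    G <- sample(2:8, 1)
    sizes <- runif(G, 2, 50)
    counts <- rmultinom(1, 200, runif(G) + 0.1)[, 1] + 1
    b <- batty_from_components(counts, sizes)
    expect_gte(b$value, log(min(sizes)) - 1e-9)
    expect_lte(b$value, log(sum(sizes)) + 1e-9)
  }
})

test_that("rescaling sizes and subtracting log c leaves Batty unchanged", {
  counts <- c(12, 5, 40)
  sizes <- c(0.004, 0.2, 0.8)  # triggers the automatic power-of-10 rescale
  b <- batty_from_components(counts, sizes, total_area = 1.004)
  expect_equal(b$meta$rescale_factor, 1000)
  for (cfac in c(10, 1e3, 2.5, 1e6)) {
    bc <- batty_from_components(counts, sizes * cfac,
                                total_area = 1.004 * cfac)
    expect_equal(bc$value - log(cfac), b$value, tolerance = 1e-9)
  }
  expect_error(batty_from_components(counts, sizes, rescale = FALSE),
               "rescale")
})

test_that("pattern-level Batty agrees with components computed by hand", {
  w <- unit_square()
  part <- voronoi_partition(w, 4, seed = 6)
  pat <- generate_csr(w, 300, seed = 12)
  g <- assign_subareas(pat, part)
  counts <- tabulate(g, nbins = 4)
  expect_equal(batty_entropy(pat, part)$value,
               batty_from_components(counts, part$sizes)$value,
               tolerance = 1e-12)
  # working-unit change: km^2 -> m^2 shifts the absolute value by log(1e6)
  b1 <- batty_entropy(pat, part)
  b6 <- batty_entropy(pat, part, size_scale = 1e6)
  expect_equal(b6$value - log(1e6), b1$value, tolerance = 1e-9)
})

test_that("LISA with neigh = 0 reduces to Shannon on sub-area probabilities", {
  w <- unit_square()
  part <- voronoi_partition(w, 6, seed = 7)
  pat <- generate_csr(w, 150, seed = 13)
  p <- tabulate(assign_subareas(pat, part), nbins = 6) / 150
  hs <- shannon_entropy(category_distribution(round(p * 150)))$value
  for (scheme in c("average", "sum")) {
    expect_equal(batty_lisa(pat, part, neigh = 0, scheme = scheme)$value,
                 hs, tolerance = 1e-12)
  }
  expect_error(batty_lisa(pat, part, neigh = 6), "neigh")
})

test_that("LISA matches the hand-enumerated 3-sub-area example", {
  # centroids on a line; p = (0.5, 0.5, 0); neigh = 1, scheme sum:
  # smoothed probs (1, 1, 0.5) so every occupied term is log(1) = 0
  part <- spentropy:::area_partition(
    ids = c("1", "2", "3"), sizes = c(1, 1, 1),
    centroids = rbind(c(0, 0), c(1, 0), c(5, 0)), source = "user",
    generators = rbind(c(0, 0), c(1, 0), c(5, 0)))
  w <- obs_window(c(-1, 6, 6, -1), c(-1, -1, 1, 1))
  pat <- point_pattern(c(0, 0, 1, 1), c(0, 0, 0, 0), w)
  res <- batty_lisa(pat, part, neigh = 1, scheme = "sum")
  expect_equal(res$value, 0, tolerance = 1e-12)
  expect_equal(res$table$smoothed_prob, c(1, 1, 0.5))
})

test_that("full averaged smoothing flattens the weights to 1/G", {
  w <- unit_square()
  part <- voronoi_partition(w, 5, seed = 19)
  pat <- generate_csr(w, 120, seed = 20)
  res <- batty_lisa(pat, part, neigh = 4, scheme = "average")
  expect_equal(res$value, log(5), tolerance = 1e-12)
  expect_equal(res$relative, 1, tolerance = 1e-12)
  # and the endpoint never sits below the unsmoothed entropy
  h0 <- batty_lisa(pat, part, neigh = 0)$value
  expect_gte(res$value, h0 - 1e-12)
})

test_that("LISA values stay non-negative; sum scheme respects log G", {
  set.seed(41)
  for (rep in 1:15) {
    G <- sample(3:9, 1)
    w <- unit_square()
    part <- voronoi_partition(w, G, seed = 500 + rep)
    pat <- generate_csr(w, 80, seed = 600 + rep)
    for (k in 0:(G - 1)) {
      hs <- batty_lisa(pat, part, neigh = k, scheme = "sum")$value
      ha <- batty_lisa(pat, part, neigh = k, scheme = "average")$value
      expect_gte(hs, -1e-12)
      expect_gte(ha, -1e-12)
      expect_lte(hs, log(G) + 1e-9)
    }
  }
})

test_that("averaged smoothing raises LISA entropy in the mean", {
  # the qualitative neighbourhood effect: averaged over patterns and
  # partitions, entropy climbs from Shannon at neigh 0 towards log G
  w <- unit_square()
  G <- 6
  hbar <- rep(0, G)
  for (rep in 1:12) {
    pat <- generate_csr(w, 100, seed = 700 + rep)
    part <- voronoi_partition(w, G, seed = 800 + rep)
    hbar <- hbar + vapply(0:(G - 1), function(k) {
      batty_lisa(pat, part, neigh = k)$value
    }, 0) / 12
  }
  expect_gt(cor(seq_len(G), hbar, method = "spearman"), 0)
  expect_gt(hbar[G], hbar[1])
})

test_that("random partition study is deterministic with honest intervals", {
  w <- unit_square()
  pat <- generate_csr(w, 150, seed = 3)
  s1 <- random_partition_study(pat, G_list = c(3, 5), reps = 4, seed = 77)
  s2 <- random_partition_study(pat, G_list = c(3, 5), reps = 4, seed = 77)
  expect_identical(s1, s2)
  one <- random_partition_study(pat, G_list = 4, reps = 1, seed = 5)
  expect_equal(one$batty_lo, one$batty_hi)
  expect_equal(one$batty_lo, one$batty_mean)
})

test_that("CSR patterns give near-maximal relative Batty entropy", {
  w <- unit_square()
  pat <- generate_csr(w, 400, seed = 23)
  st <- random_partition_study(pat, G_list = 10, reps = 10, seed = 29)
  expect_gt(st$batty_mean, 0.9)
})
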