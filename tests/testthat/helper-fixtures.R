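# shared fixtures and independent oracles, built in code at test time

unit_square <- function() obs_window(c(0, 1, 1, 0), c(0, 0, 1, 1))

l_shaped_window <- function() {
  obs_window(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 2, 2))
}

# the hand-worked 4-corner pattern: unit-square corners, marks placed so the
# two diagonal pairs are homogeneous (a-a and b-b) and the four side pairs
# are all mixed
four_corner_pattern <- function() {
  point_pattern(c(0, 1, 1, 0), c(0, 0, 1, 1), unit_square(),
                marks = c("a", "b", "a", "b"))
}

random_marked_pattern <- function(n, seed, labs = c("u", "v", "w")) {
  set.seed(seed)
  point_pattern(runif(n, 0, 10), runif(n, 0, 10),
                obs_window(c(0, 10, 10, 0), c(0, 0, 10, 10)),
                marks = sample(labs, n, replace = TRUE))
}

write_square_wkt <- function(path = tempfile(fileext = ".wkt")) {
  writeLines("POLYGON ((0 0, 1 0, 1 1, 0 1, 0 0))", path)
  path
}

write_points_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# O(n^2) brute-force ordered-couple counts within distance d, enumerating
# unordered pairs in canonical (x, y, input order) order — written directly
# from the definition, independent of the package's blocked enumeration
brute_force_couples <- function(x, y, marks, d, labs = unique(marks)) {
  ord <- order(x, y, seq_along(x))
  x <- x[ord]; y <- y[ord]; marks <- marks[ord]
  I <- length(labs)
  acc <- matrix(0, I, I, dimnames = list(labs, labs))
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= d) {
        acc[marks[i], marks[j]] <- acc[marks[i], marks[j]] + 1
      }
    }
  }
  acc
}

# brute-force decomposition oracle: per-class unordered-pair tables from a
# plain double loop, then the textbook mutual-information identities
brute_force_decomposition <- function(x, y, marks, breaks) {
  ord <- order(x, y, seq_along(x))   # canonical order fixes the label order
  x <- x[ord]; y <- y[ord]; marks <- marks[ord]
  labs <- unique(marks)
  I <- length(labs)
  pl <- character(0)
  for (a in seq_len(I)) for (b in a:I) {
    pl <- c(pl, paste(labs[a], labs[b], sep = "-"))
  }
  pkey <- function(a, b) {
    ab <- sort(c(match(a, labs), match(b, labs)))
    paste(labs[ab[1]], labs[ab[2]], sep = "-")
  }
  K <- length(breaks) - 1
  counts <- matrix(0, K, length(pl), dimnames = list(NULL, pl))
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dd <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      k <- if (dd == 0) 1 else max(1, findInterval(dd, breaks, left.open = TRUE))
      counts[k, pkey(marks[i], marks[j])] <-
        counts[k, pkey(marks[i], marks[j])] + 1
    }
  }
  total <- sum(counts)
  pZ <- colSums(counts) / total
  H_Z <- -sum(pZ[pZ > 0] * log(pZ[pZ > 0]))
  nk <- rowSums(counts)
  MI <- 0; resid <- 0
  for (k in which(nk > 0)) {
    pk <- counts[k, ] / nk[k]
    pos <- pk > 0
    MI <- MI + nk[k] / total * sum(pk[pos] * log(pk[pos] / pZ[pos]))
    resid <- resid + nk[k] / total * -sum(pk[pos] * log(pk[pos]))
  }
  list(H_Z = H_Z, MI = MI, residual = resid, class_counts = counts)
}
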