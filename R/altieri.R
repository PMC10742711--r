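#' Default distance classes for the decomposable entropy
#'
#' For square-cell grids the default breaks are `(0, c], (c, 2c], (2c, Inf)`
#' with `c` the cell width: the first class holds the 4 rook neighbours (at
#' distance `c`), the second the next 12 cells (diagonals at `c*sqrt(2)` and
#' second-order axials at `2c`), and the third is the residual class.
#' Rectangular cells have no such canonical neighbour rings, so the grid
#' default refuses and breaks must be supplied. For point data the finite
#' breaks are the deciles (10%..90%, type-7) of the nearest-neighbour
#' distance distribution, deduplicated, starting at 0, plus the residual
#' class to infinity.
#'
#' @param data a [point_pattern()] with `n >= 2` or a [spat_raster()].
#' @return Numeric vector of breaks `0 = b_0 < b_1 < ... < Inf` defining
#'   left-open/right-closed classes `(b_{k-1}, b_k]`.
#' @export
default_breaks <- function(data) {
  if (inherits(data, "spat_raster")) {
    if (data$xstep != data$ystep) {
      stop("no default distance classes for rectangular cells; ",
           "supply breaks explicitly")
    }
    cc <- data$xstep
    return(c(0, cc, 2 * cc, Inf))
  }
  stopifnot(inherits(data, "spat_ppp"))
  if (data$n < 2) stop("need at least 2 points")
  nn <- distance_summaries(data)$nn_distances
  br <- unique(quantile(nn, probs = seq(0.1, 0.9, by = 0.1), type = 7,
                        names = FALSE))
  br <- br[br > 0]
  c(0, br, Inf)
}

# unordered-pair index helper: I labels -> I(I+1)/2 pair labels
.pair_labels <- function(labs) {
  I <- length(labs)
  out <- character(0)
  for (a in seq_len(I)) for (b in a:I) {
    out <- c(out, paste(labs[a], labs[b], sep = "-"))
  }
  out
}

.pair_index <- function(a, b, I) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  # index of unordered pair (lo, hi) in the a <= b row-wise enumeration
  (lo - 1L) * (I + 1L) - (lo - 1L) * lo / 2 + hi - lo + 1L
}

#' Decomposition of the pair entropy into spatial and residual parts
#'
#' Builds the unordered-pair variable `Z` over all pairs of observations
#' (every pair, at every distance) and the distance-class variable `W`, and
#' decomposes Shannon's entropy of `Z` as
#' `H(Z) = MI(Z, W) + H(Z)_W = sum_k p(w_k) [PI(Z|w_k) + H(Z|w_k)]`,
#' where `MI` is the spatial mutual information (diversity explained by
#' distance classes) and `H(Z)_W` the spatial residual entropy. Each
#' partial information term `PI(Z|w_k)` is a Kullback-Leibler divergence of
#' the within-class pair distribution from the global one, hence
#' non-negative. Classes are left-open/right-closed `(b_{k-1}, b_k]`;
#' coincident observations (distance 0) fall in the first class; empty
#' classes are dropped with a warning.
#'
#' @param data a marked [point_pattern()] or a categorical [spat_raster()]
#'   with at least 2 observations.
#' @param breaks distance-class breaks as in [default_breaks()] (used when
#'   `NULL`); the first break must be 0 and the last `Inf` (both are added
#'   if missing).
#' @return An object of class `"entropy_decomposition"`: list with `H_Z`,
#'   `MI`, `residual`, `breaks`, `pair_labels`, `global` (pair probabilities),
#'   and `classes`, a data.frame with one row per non-empty class
#'   (`class`, `lower`, `upper`, `pairs`, `weight`, `PI`, `H`), plus
#'   `class_tables` (within-class pair frequencies).
#' @examples
#' w <- obs_window(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' p <- point_pattern(c(0, 1, 1, 0), c(0, 0, 1, 1), w,
#'                    marks = c("a", "b", "a", "b"))
#' altieri_decomposition(p, breaks = c(0, 1, Inf))
#' @export
altieri_decomposition <- function(data, breaks = NULL) {
  b <- .pair_basis(data)
  n <- length(b$x)
  if (n < 2) stop("need at least 2 observations")
  if (is.null(breaks)) breaks <- default_breaks(data)
  breaks <- sort(unique(as.numeric(breaks)))
  if (breaks[1] != 0) breaks <- c(0, breaks)
  if (is.finite(breaks[length(breaks)])) breaks <- c(breaks, Inf)
  K <- length(breaks) - 1
  I <- length(b$labs)
  f <- match(b$cat, b$labs)
  R <- I * (I + 1) / 2
  # all unordered pairs: distances and pair-category indices
  dd <- as.vector(dist(cbind(b$x, b$y)))
  ii <- rep.int(seq_len(n - 1), (n - 1):1)
  jj <- sequence((n - 1):1) + ii
  z <- .pair_index(f[ii], f[jj], I)
  k <- findInterval(dd, breaks, left.open = TRUE)
  k[dd == 0] <- 1L            # coincident observations -> first class
  k <- pmin(k, K)
  total <- length(dd)
  global_counts <- tabulate(z, nbins = R)
  pZ <- global_counts / total
  H_Z <- .plogp(pZ)
  class_counts <- matrix(0, K, R)
  tk <- table(factor(k, levels = seq_len(K)), factor(z, levels = seq_len(R)))
  class_counts <- unclass(tk)
  nk <- rowSums(class_counts)
  empty <- nk == 0
  if (any(empty)) {
    warning(sum(empty), " empty distance class(es) dropped")
  }
  keep <- which(!empty)
  pW <- nk[keep] / total
  PI <- numeric(length(keep)); Hk <- numeric(length(keep))
  for (m in seq_along(keep)) {
    pk <- class_counts[keep[m], ] / nk[keep[m]]
    pos <- pk > 0
    PI[m] <- sum(pk[pos] * log(pk[pos] / pZ[pos]))
    Hk[m] <- .plogp(pk)
  }
  MI <- sum(pW * PI)
  resid <- sum(pW * Hk)
  labels <- .pair_labels(b$labs)
  classes <- data.frame(class = seq_along(keep),
                        lower = breaks[keep], upper = breaks[keep + 1],
                        pairs = nk[keep], weight = pW,
                        PI = PI, H = Hk)
  cls_tab <- lapply(seq_along(keep), function(m) {
    data.frame(pair = labels, count = class_counts[keep[m], ],
               prob = class_counts[keep[m], ] / nk[keep[m]],
               stringsAsFactors = FALSE)
  })
  structure(list(H_Z = H_Z, MI = MI, residual = resid,
                 breaks = breaks, pair_labels = labels,
                 global = data.frame(pair = labels, count = global_counts,
                                     prob = pZ, stringsAsFactors = FALSE),
                 classes = classes, class_tables = cls_tab,
                 n = n, total_pairs = total),
            class = "entropy_decomposition")
}

#' @export
print.entropy_decomposition <- function(x, ...) {
  cat("Decomposable spatial entropy (", x$n, " observations, ",
      x$total_pairs, " pairs)\n", sep = "")
  cat(sprintf("  H(Z) = %.4f = MI %.4f + residual %.4f nats\n",
              x$H_Z, x$MI, x$residual))
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' Per-class spatial/residual shares of the decomposition
#'
#' For each distance class, the share of the class's total information that
#' is spatial, `PI / (PI + H)`, and residual, `H / (PI + H)` (defined as
#' 0 and 1 when both terms vanish), together with the class weights — the
#' quantities behind the standard stacked bar plot of the decomposition.
#'
#' @param result an `"entropy_decomposition"`.
#' @return data.frame with `class`, `lower`, `upper`, `weight`,
#'   `spatial_share`, `residual_share`.
#' @export
decomposition_profile <- function(result) {
  stopifnot(inherits(result, "entropy_decomposition"))
  cl <- result$classes
  tot <- cl$PI + cl$H
  sp <- ifelse(tot > 0, cl$PI / tot, 0)
  data.frame(class = cl$class, lower = cl$lower, upper = cl$upper,
             weight = cl$weight,
             spatial_share = sp, residual_share = 1 - sp)
}
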