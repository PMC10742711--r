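#' Completely spatially random (CSR) point pattern
#'
#' `n` i.i.d. uniform points in the window via seeded rejection sampling
#' from the bounding box (base R Mersenne-Twister). CSR is the null model
#' against which spatial structure is judged: under CSR the expected point
#' share of any sub-area is proportional to its size, and independently
#' assigned marks carry no spatial information.
#'
#' @param window a [obs_window()].
#' @param n number of points (>= 0).
#' @param seed integer seed.
#' @param mark_probs optional named probability vector; marks are then drawn
#'   independently per point.
#' @return A [point_pattern()].
#' @examples
#' w <- obs_window(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' generate_csr(w, 100, seed = 1, mark_probs = c(a = .5, b = .5))
#' @export
generate_csr <- function(window, n, seed = 1, mark_probs = NULL) {
  stopifnot(inherits(window, "spat_window"), n >= 0)
  set.seed(seed)
  xy <- if (n > 0) runif_in_window(window, n) else matrix(0, 0, 2)
  marks <- .draw_marks(n, mark_probs)
  point_pattern(xy[, 1], xy[, 2], window, marks = marks, check = FALSE)
}

.draw_marks <- function(n, probs) {
  if (is.null(probs)) return(NULL)
  if (abs(sum(probs) - 1) > 1e-9 || any(probs < 0)) {
    stop("mark probabilities must be non-negative and sum to 1")
  }
  labs <- if (!is.null(names(probs))) names(probs) else
    as.character(seq_along(probs))
  if (n == 0) return(character(0))
  sample(labs, n, replace = TRUE, prob = probs)
}

#' Thomas-like clustered point pattern
#'
#' Seeded parent points uniform in the window; each parent gets
#' `Poisson(offspring_mean)` offspring displaced by an isotropic Gaussian
#' with standard deviation `spread`, retained only if they fall inside the
#' window. Marks are either drawn independently per offspring or inherited
#' from a parent-level label, which plants short-range mark association
#' that the decomposable entropy should detect as positive mutual
#' information.
#'
#' @param window a [obs_window()].
#' @param parents number of parent points.
#' @param offspring_mean mean offspring per parent (>= 0).
#' @param spread Gaussian displacement SD (coordinate units).
#' @param seed integer seed.
#' @param mark_probs optional probability vector for mark labels.
#' @param mark_rule `"independent"` (per offspring) or `"inherited"` (per
#'   parent); ignored when `mark_probs` is `NULL`.
#' @param keep_parents include the parent points themselves (default
#'   `FALSE`).
#' @return A [point_pattern()].
#' @export
generate_clustered <- function(window, parents, offspring_mean, spread,
                               seed = 1, mark_probs = NULL,
                               mark_rule = c("independent", "inherited"),
                               keep_parents = FALSE) {
  stopifnot(inherits(window, "spat_window"), parents >= 1)
  mark_rule <- match.arg(mark_rule)
  set.seed(seed)
  par_xy <- runif_in_window(window, parents)
  par_marks <- .draw_marks(parents, mark_probs)
  noff <- rpois(parents, offspring_mean)
  xs <- ys <- numeric(0); ms <- character(0)
  for (i in seq_len(parents)) {
    if (noff[i] == 0) next
    ox <- par_xy[i, 1] + rnorm(noff[i], 0, spread)
    oy <- par_xy[i, 2] + rnorm(noff[i], 0, spread)
    keep <- points_in_window(window, ox, oy)
    xs <- c(xs, ox[keep]); ys <- c(ys, oy[keep])
    if (!is.null(mark_probs)) {
      ms <- c(ms, if (mark_rule == "inherited") {
        rep(par_marks[i], sum(keep))
      } else {
        .draw_marks(sum(keep), mark_probs)
      })
    }
  }
  if (keep_parents) {
    xs <- c(par_xy[, 1], xs); ys <- c(par_xy[, 2], ys)
    if (!is.null(mark_probs)) ms <- c(par_marks, ms)
  }
  point_pattern(xs, ys, window,
                marks = if (is.null(mark_probs)) NULL else ms,
                check = FALSE)
}

#' Spatially autocorrelated binary raster
#'
#' Thresholds a seeded Gaussian noise field, optionally smoothed with a
#' Gaussian kernel of standard deviation `smoothing` cells, at its
#' `(1 - p1)` type-7 quantile: cells above the threshold get category
#' `"1"`, the rest `"0"`, so the marginal frequency of `"1"` is
#' approximately `p1` while spatial clumping grows with `smoothing`
#' (`smoothing = 0` gives i.i.d. cells).
#'
#' @param nrows,ncols grid dimensions.
#' @param p1 target marginal frequency of category `"1"` in `[0, 1]`.
#' @param smoothing Gaussian kernel SD in cell units (0 = no smoothing).
#' @param seed integer seed.
#' @return A binary [spat_raster()] with unit square cells at the origin.
#' @export
generate_autocorrelated_raster <- function(nrows, ncols, p1, smoothing = 0,
                                           seed = 1) {
  stopifnot(nrows >= 1, ncols >= 1, p1 >= 0, p1 <= 1)
  set.seed(seed)
  z <- matrix(rnorm(nrows * ncols), nrows, ncols)
  if (smoothing > 0) z <- .gauss_smooth(z, smoothing)
  if (p1 <= 0) {
    m <- matrix("0", nrows, ncols)
  } else if (p1 >= 1) {
    m <- matrix("1", nrows, ncols)
  } else {
    thr <- quantile(z, probs = 1 - p1, type = 7, names = FALSE)
    m <- matrix(ifelse(z > thr, "1", "0"), nrows, ncols)
  }
  spat_raster(m)
}

# Gaussian kernel smoothing with edge renormalisation
.gauss_smooth <- function(z, sigma) {
  r <- ceiling(3 * sigma)
  off <- -r:r
  k1 <- exp(-off^2 / (2 * sigma^2))
  nr <- nrow(z); nc <- ncol(z)
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  for (di in off) for (dj in off) {
    wt <- k1[di + r + 1] * k1[dj + r + 1]
    si <- max(1, 1 - di):min(nr, nr - di)
    sj <- max(1, 1 - dj):min(nc, nc - dj)
    num[si, sj] <- num[si, sj] + wt * z[si + di, sj + dj]
    den[si, sj] <- den[si, sj] + wt
  }
  num / den
}

#' Grid-resolution sensitivity study
#'
#' Pixellates a point pattern at each requested resolution and computes the
#' requested presence/absence measures, tracing how the modifiable areal
#' unit problem drives the indices: as the grid is refined the occupied
#' fraction collapses and every entropy built on the presence variable (or
#' its couples) decays towards zero, while contagion rises towards one.
#'
#' @param pattern a [point_pattern()].
#' @param resolutions integer vector; each value `m` gives an `m x m` grid.
#' @param measures subset of `"shannon"`, `"oneill"`, `"contagion"`,
#'   `"parresol"`, `"leibovici"`, `"shannon_marks"` (Shannon on the point
#'   marks, resolution-independent; errors on an unmarked pattern).
#' @param d distance for the `"leibovici"` measure, in physical units
#'   (required if requested).
#' @return data.frame with one row per resolution: `resolution`,
#'   `occupied_cells`, `valid_cells`, `occupied_fraction` and one column
#'   per relative measure value.
#' @export
resolution_sensitivity <- function(pattern, resolutions,
                                   measures = c("shannon", "oneill",
                                                "contagion"),
                                   d = NULL) {
  stopifnot(inherits(pattern, "spat_ppp"))
  known <- c("shannon", "oneill", "contagion", "parresol", "leibovici",
             "shannon_marks")
  bad <- setdiff(measures, known)
  if (length(bad)) stop("unknown measure(s): ", paste(bad, collapse = ", "))
  if ("leibovici" %in% measures && is.null(d)) {
    stop("measure 'leibovici' needs a distance d")
  }
  if ("shannon_marks" %in% measures && is.null(pattern$marks)) {
    stop("measure 'shannon_marks' needs a marked pattern")
  }
  rows <- lapply(resolutions, function(m) {
    r <- pixellate_pattern(pattern, m, m)
    nvalid <- sum(!is.na(r$values))
    nocc <- sum(r$values == "1", na.rm = TRUE)
    row <- data.frame(resolution = m, occupied_cells = nocc,
                      valid_cells = nvalid,
                      occupied_fraction = nocc / nvalid)
    for (ms in measures) {
      row[[ms]] <- switch(ms,
        shannon = shannon_entropy(r)$relative,
        oneill = oneill_entropy(r)$relative,
        contagion = contagion(r)$value,
        parresol = parresol_edwards(r)$relative,
        leibovici = leibovici_entropy(r, d)$relative,
        shannon_marks = shannon_entropy(pattern)$relative)
    }
    row
  })
  do.call(rbind, rows)
}
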