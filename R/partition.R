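#' Partition of an observation window into sub-areas
#'
#' Internal constructor for the `"area_partition"` class: `G` sub-areas with
#' identifiers, positive sizes `T_g`, centroids, and enough geometry to
#' assign every point of a pattern to exactly one sub-area. Built by
#' [voronoi_partition()], [quantile_partition()], [raster_class_partition()]
#' or [read_partition()].
#'
#' @param ids character vector of sub-area identifiers.
#' @param sizes numeric vector of sub-area sizes (squared coordinate unit).
#' @param centroids G x 2 matrix of sub-area centroids.
#' @param source one of `"voronoi"`, `"covariate_quantile"`,
#'   `"raster_classes"`, `"user"`.
#' @param polygons optional list (one element per sub-area) of contour lists
#'   (`list(x=, y=)`) for polygon-based partitions.
#' @param generators optional G x 2 matrix of Voronoi generator points.
#' @param class_raster optional integer matrix mapping raster cells to
#'   sub-area index (`NA` = NODATA), plus `raster` for its geometry.
#' @param raster optional the underlying [spat_raster()].
#' @keywords internal
area_partition <- function(ids, sizes, centroids, source,
                           polygons = NULL, generators = NULL,
                           class_raster = NULL, raster = NULL) {
  if (any(sizes <= 0)) stop("all sub-area sizes must be positive")
  structure(list(ids = as.character(ids), G = length(ids),
                 sizes = as.numeric(sizes),
                 centroids = matrix(as.numeric(centroids), ncol = 2),
                 source = source, polygons = polygons,
                 generators = generators, class_raster = class_raster,
                 raster = raster),
            class = "area_partition")
}

#' @export
print.area_partition <- function(x, ...) {
  cat("Area partition (", x$source, "): G = ", x$G,
      ", total size ", format(sum(x$sizes)), "\n", sep = "")
  invisible(x)
}

#' Random Voronoi partition of a window
#'
#' Draws `G` generator points uniformly in the polygon (seeded rejection
#' sampling from the bounding box), builds their Voronoi tessellation, and
#' clips each tile to the window, so sub-area sizes sum to the window area.
#' Generators closer than a degeneracy tolerance are resampled (with a
#' message). Identical `(window, G, seed)` give an identical partition.
#'
#' @param window a [obs_window()].
#' @param G number of sub-areas (>= 1).
#' @param seed integer seed for the generator draw.
#' @param generators optional G x 2 matrix of fixed generator points inside
#'   the window, bypassing the random draw.
#' @return An `"area_partition"` with `source = "voronoi"`.
#' @examples
#' w <- obs_window(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' p <- voronoi_partition(w, G = 4, seed = 1)
#' sum(p$sizes)  # equals window_area(w)
#' @export
voronoi_partition <- function(window, G, seed = 1, generators = NULL) {
  stopifnot(inherits(window, "spat_window"))
  G <- as.integer(G)
  if (G < 1) stop("G must be >= 1")
  if (is.null(generators)) {
    set.seed(seed)
    generators <- runif_in_window(window, G)
    tol <- 1e-8 * max(diff(window$bbox[c("xmin", "xmax")]),
                      diff(window$bbox[c("ymin", "ymax")]))
    while (G > 1) {
      dm <- as.matrix(dist(generators)); diag(dm) <- Inf
      cp <- which(dm < tol, arr.ind = TRUE)
      bad <- unique(cp[cp[, 1] < cp[, 2], 2])  # keep the first of each clash
      if (length(bad) == 0) break
      message("resampling ", length(bad), " degenerate Voronoi generator(s)")
      generators[bad, ] <- runif_in_window(window, length(bad))
    }
  } else {
    generators <- matrix(as.numeric(generators), ncol = 2)
    if (nrow(generators) != G) stop("generators must be a G x 2 matrix")
    if (!all(points_in_window(window, generators[, 1], generators[, 2]))) {
      stop("all generator points must lie inside the window")
    }
  }
  wpoly <- list(list(x = window$boundary[, 1], y = window$boundary[, 2]))
  if (G == 1) {
    return(area_partition(ids = "1", sizes = window$area,
                          centroids = rbind(polygon_centroid(window$boundary)),
                          source = "voronoi", polygons = list(wpoly),
                          generators = generators))
  }
  bb <- window$bbox
  pad <- 1e-6 * max(bb["xmax"] - bb["xmin"], bb["ymax"] - bb["ymin"])
  dd <- deldir::deldir(generators[, 1], generators[, 2],
                       rw = c(bb["xmin"] - pad, bb["xmax"] + pad,
                              bb["ymin"] - pad, bb["ymax"] + pad),
                       suppressMsge = TRUE)
  tiles <- deldir::tile.list(dd)
  polys <- vector("list", G)
  sizes <- numeric(G)
  cents <- matrix(0, G, 2)
  for (g in seq_len(G)) {
    tile <- list(list(x = tiles[[g]]$x, y = tiles[[g]]$y))
    clipped <- polyclip::polyclip(tile, wpoly, op = "intersection")
    if (length(clipped) == 0) stop("empty Voronoi cell after clipping")
    polys[[g]] <- clipped
    a <- vapply(clipped, function(p) signed_area(cbind(p$x, p$y)), 0)
    sizes[g] <- abs(sum(a))
    cw <- t(vapply(clipped, function(p) polygon_centroid(cbind(p$x, p$y)),
                   numeric(2)))
    cents[g, ] <- colSums(cw * a) / sum(a)
  }
  part <- area_partition(ids = as.character(seq_len(G)), sizes = sizes,
                         centroids = cents, source = "voronoi",
                         polygons = polys, generators = generators)
  rel <- abs(sum(sizes) - window$area) / window$area
  if (rel > 1e-6) {
    warning("Voronoi sub-area sizes sum to ", sum(sizes),
            " vs window area ", window$area)
  }
  part
}

#' Uniform points in a polygon by rejection sampling
#' @keywords internal
runif_in_window <- function(window, n) {
  bb <- window$bbox
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 16L)
    x <- runif(m, bb["xmin"], bb["xmax"])
    y <- runif(m, bb["ymin"], bb["ymax"])
    keep <- which(points_in_window(window, x, y))
    take <- head(keep, n - got)
    if (length(take)) {
      out[got + seq_along(take), ] <- cbind(x[take], y[take])
      got <- got + length(take)
    }
  }
  out
}

#' Partition from the quantile classes of a continuous raster covariate
#'
#' Cuts the valid cells of a numeric raster (e.g. elevation) into `k` classes
#' at the empirical type-7 k-quantiles; intervals are left-open/right-closed
#' with the lowest closed at the minimum. Each class becomes a sub-area whose
#' size is its cell count times the cell area.
#'
#' @param raster a numeric-valued [spat_raster()].
#' @param k number of classes (>= 2); `k = 4` gives quartile classes.
#' @param name covariate name used in error messages and sub-area ids.
#' @return An `"area_partition"` with `source = "covariate_quantile"`.
#' @export
quantile_partition <- function(raster, k = 4, name = "covariate") {
  stopifnot(inherits(raster, "spat_raster"))
  if (k < 2) stop("k must be >= 2")
  vals <- raster$values
  if (!is.numeric(vals)) {
    vals <- suppressWarnings(matrix(as.numeric(vals), nrow(vals)))
    if (any(is.na(vals) & !is.na(raster$values))) {
      stop("quantile partition needs a numeric raster for ", name)
    }
  }
  v <- vals[!is.na(vals)]
  if (length(v) == 0) stop("raster has no valid cells")
  br <- quantile(v, probs = seq(0, 1, length.out = k + 1), type = 7)
  if (length(unique(br)) < k + 1) {
    stop("covariate '", name, "' has too few distinct values for ",
         k, " quantile classes")
  }
  cls <- matrix(as.integer(cut(vals, breaks = br, include.lowest = TRUE,
                               right = TRUE)),
                raster$nrows, raster$ncols)
  .partition_from_classes(raster, cls,
                          ids = paste0(name, "_q", seq_len(k)),
                          source = "covariate_quantile")
}

#' Partition from the categories of a categorical raster
#'
#' One sub-area per observed category (e.g. vegetation type); size equals
#' cell count times cell area, centroid is the mean of member cell
#' centroids.
#'
#' @param raster a categorical [spat_raster()].
#' @return An `"area_partition"` with `source = "raster_classes"`.
#' @export
raster_class_partition <- function(raster) {
  stopifnot(inherits(raster, "spat_raster"))
  v <- raster$values
  if (all(is.na(v))) stop("raster has no valid cells")
  labs <- unique(v[!is.na(v)])
  cls <- matrix(match(v, labs), raster$nrows, raster$ncols)
  .partition_from_classes(raster, cls, ids = as.character(labs),
                          source = "raster_classes")
}

.partition_from_classes <- function(raster, cls, ids, source) {
  cell_area <- raster$xstep * raster$ystep
  G <- length(ids)
  counts <- tabulate(cls[!is.na(cls)], nbins = G)
  keep <- counts > 0
  idx <- which(!is.na(cls), arr.ind = TRUE)
  cx <- raster$x0 + (idx[, "col"] - 0.5) * raster$xstep
  cy <- raster$y0 + (idx[, "row"] - 0.5) * raster$ystep
  ci <- cls[idx]
  cents <- cbind(tapply(cx, ci, mean)[as.character(seq_len(G))],
                 tapply(cy, ci, mean)[as.character(seq_len(G))])
  cls_kept <- matrix(match(cls, which(keep)), nrow(cls), ncol(cls))
  area_partition(ids = ids[keep], sizes = counts[keep] * cell_area,
                 centroids = cents[keep, , drop = FALSE], source = source,
                 class_raster = cls_kept, raster = raster)
}

#' Read a partition from GeoJSON polygons or a categorical raster
#'
#' GeoJSON input must be a `FeatureCollection` of `Polygon` features, each
#' with an `"id"` property; raster input (`.asc`) is passed to
#' [raster_class_partition()].
#'
#' @param path file path.
#' @return An `"area_partition"`.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("partition file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!(grepl("\\.(geo)?json$", tolower(path)) ||
        substr(trimws(txt), 1, 1) == "{")) {
    return(raster_class_partition(read_ascii_grid(path)))
  }
  g <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (is.null(g$type) || g$type != "FeatureCollection") {
    stop("partition GeoJSON must be a FeatureCollection")
  }
  feats <- g$features
  if (length(feats) == 0) stop("partition FeatureCollection is empty")
  ids <- character(length(feats))
  polys <- vector("list", length(feats))
  sizes <- numeric(length(feats))
  cents <- matrix(0, length(feats), 2)
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    ids[i] <- if (!is.null(f$properties$id)) as.character(f$properties$id) else
      as.character(i)
    if (f$geometry$type != "Polygon") stop("partition features must be Polygons")
    ring <- f$geometry$coordinates[[1]]
    xy <- t(vapply(ring, function(p) as.numeric(p[1:2]), numeric(2)))
    if (all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
    polys[[i]] <- list(list(x = xy[, 1], y = xy[, 2]))
    sizes[i] <- shoelace_area(xy)
    cents[i, ] <- polygon_centroid(xy)
  }
  area_partition(ids = ids, sizes = sizes, centroids = cents,
                 source = "user", polygons = polys)
}

#' Assign pattern points to partition sub-areas
#'
#' Voronoi partitions assign by nearest generator (ties to the lowest
#' sub-area id); polygon partitions by point-in-polygon (boundary counts as
#' inside, first matching sub-area wins); raster-based partitions by the
#' half-open cell containing each point.
#'
#' @param pattern a [point_pattern()].
#' @param partition an `"area_partition"`.
#' @return Integer vector of sub-area indices (length `pattern$n`); errors if
#'   any point is not covered.
#' @export
assign_subareas <- function(pattern, partition) {
  stopifnot(inherits(pattern, "spat_ppp"), inherits(partition, "area_partition"))
  n <- pattern$n
  if (n == 0) return(integer(0))
  if (!is.null(partition$generators)) {
    d2 <- outer(pattern$x, partition$generators[, 1], "-")^2 +
      outer(pattern$y, partition$generators[, 2], "-")^2
    return(max.col(-d2, ties.method = "first"))
  }
  if (!is.null(partition$class_raster)) {
    r <- partition$raster
    cc <- pmin(floor((pattern$x - r$x0) / r$xstep) + 1L, r$ncols)
    rr <- pmin(floor((pattern$y - r$y0) / r$ystep) + 1L, r$nrows)
    bad <- cc < 1 | rr < 1 | cc > r$ncols | rr > r$nrows
    if (any(bad)) stop(sum(bad), " point(s) outside the partition raster")
    g <- partition$class_raster[cbind(rr, cc)]
    if (anyNA(g)) stop(sum(is.na(g)), " point(s) fall on NODATA partition cells")
    return(as.integer(g))
  }
  out <- integer(n)
  remaining <- seq_len(n)
  for (g in seq_len(partition$G)) {
    if (!length(remaining)) break
    inside <- rep(FALSE, length(remaining))
    for (ctr in partition$polygons[[g]]) {
      inside <- inside | sp::point.in.polygon(
        pattern$x[remaining], pattern$y[remaining], ctr$x, ctr$y) > 0
    }
    out[remaining[inside]] <- g
    remaining <- remaining[!inside]
  }
  if (length(remaining)) {
    stop(length(remaining), " point(s) not covered by any sub-area")
  }
  out
}
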