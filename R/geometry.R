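#' Planar observation window
#'
#' An observation window is the simple (non-self-intersecting) polygon within
#' which events could have been recorded. Coordinates are planar/projected
#' (e.g. UTM metres); all distances in the package are Euclidean in these
#' units, and the window area carries the squared unit.
#'
#' @param x numeric vector of vertex x coordinates, or a two-column matrix of
#'   vertices. The ring may be open or closed (a repeated last vertex is
#'   dropped); orientation is irrelevant.
#' @param y numeric vector of vertex y coordinates when `x` is a vector.
#' @return An object of class `"spat_window"`: a list with `boundary` (open
#'   vertex ring, n x 2 matrix), `area` and `bbox` (`xmin,xmax,ymin,ymax`).
#' @examples
#' w <- obs_window(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' window_area(w)
#' @export
obs_window <- function(x, y = NULL) {
  if (is.matrix(x) || is.data.frame(x)) {
    v <- as.matrix(x)[, 1:2, drop = FALSE]
  } else {
    v <- cbind(as.numeric(x), as.numeric(y))
  }
  storage.mode(v) <- "double"
  if (anyNA(v)) stop("window vertices contain NA")
  n <- nrow(v)
  if (n >= 2 && all(v[1, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  if (nrow(v) < 3) stop("a polygon needs at least 3 distinct vertices")
  if (!.polygon_is_simple(v)) stop("window polygon is self-intersecting")
  a <- shoelace_area(v)
  if (a <= 0) stop("window polygon has zero area")
  structure(list(
    boundary = unname(v),
    area = a,
    bbox = c(xmin = min(v[, 1]), xmax = max(v[, 1]),
             ymin = min(v[, 2]), ymax = max(v[, 2]))
  ), class = "spat_window")
}

#' @export
print.spat_window <- function(x, ...) {
  cat("Observation window:", nrow(x$boundary), "vertices, area",
      format(x$area), "\n")
  invisible(x)
}

#' Area of an observation window
#'
#' Shoelace (Gauss) area of the boundary polygon; positive regardless of
#' vertex orientation.
#'
#' @param window a [obs_window()] object.
#' @return The polygon area (squared coordinate unit).
#' @export
window_area <- function(window) {
  stopifnot(inherits(window, "spat_window"))
  window$area
}

#' Shoelace area of a vertex ring
#' @param v two-column matrix of vertices (open ring).
#' @return absolute polygon area.
#' @keywords internal
shoelace_area <- function(v) {
  abs(signed_area(v))
}

signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# simple-polygon test: no two non-adjacent edges intersect
.polygon_is_simple <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next
      if (.segments_intersect(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

.segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on <- function(p, q, r) {
    d(p, q, r) == 0 &&
      min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
      min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
  }
  on(p3, p4, p1) || on(p3, p4, p2) || on(p1, p2, p3) || on(p1, p2, p4)
}

#' Test whether points fall inside a window
#'
#' Points exactly on the boundary count as inside, so observations on the
#' border are never silently lost.
#'
#' @param window a [obs_window()] object.
#' @param x,y numeric coordinate vectors.
#' @return logical vector.
#' @export
points_in_window <- function(window, x, y) {
  stopifnot(inherits(window, "spat_window"))
  b <- window$boundary
  sp::point.in.polygon(x, y, b[, 1], b[, 2]) > 0
}

#' Read an observation window from WKT or GeoJSON
#'
#' Accepts a text file holding a single `POLYGON` in WKT, or a GeoJSON
#' `Polygon` geometry / `Feature` / one-feature `FeatureCollection`. Only the
#' exterior ring is used; interior rings (holes) are rejected.
#'
#' @param path file path. Files ending in `.json`/`.geojson`, or whose text
#'   starts with an opening brace, are parsed as GeoJSON; anything else as
#'   WKT.
#' @return A [obs_window()] object.
#' @export
read_window <- function(path) {
  if (!file.exists(path)) stop("window file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  first <- substr(trimws(txt), 1, 1)
  if (grepl("\\.(geo)?json$", tolower(path)) || first == "{") {
    ring <- .geojson_polygon_ring(jsonlite::fromJSON(txt, simplifyMatrix = TRUE))
  } else {
    ring <- parse_wkt_polygon(txt)
  }
  obs_window(ring)
}

#' Parse a WKT POLYGON string
#' @param txt character scalar holding the WKT POLYGON text.
#' @return matrix of exterior-ring vertices.
#' @keywords internal
parse_wkt_polygon <- function(txt) {
  txt <- trimws(txt)
  if (!grepl("^POLYGON", txt, ignore.case = TRUE)) {
    stop("expected a WKT POLYGON, got: ", substr(txt, 1, 30))
  }
  body <- sub("^POLYGON\\s*", "", txt, ignore.case = TRUE)
  rings <- regmatches(body, gregexpr("\\(([^()]+)\\)", body))[[1]]
  if (length(rings) == 0) stop("malformed WKT POLYGON: no ring found")
  if (length(rings) > 1) stop("WKT POLYGON with interior rings is not supported")
  coords <- trimws(strsplit(gsub("[()]", "", rings[1]), ",")[[1]])
  xy <- t(vapply(coords, function(s) {
    p <- as.numeric(strsplit(s, "\\s+")[[1]])
    if (length(p) < 2 || anyNA(p)) stop("malformed WKT coordinate: ", s)
    p[1:2]
  }, numeric(2)))
  unname(xy)
}

.geojson_polygon_ring <- function(g) {
  if (!is.null(g$type) && g$type == "FeatureCollection") {
    if (length(g$features) < 1) stop("GeoJSON FeatureCollection is empty")
    co <- g$features$geometry$coordinates[[1]]
    ty <- g$features$geometry$type[1]
  } else if (!is.null(g$type) && g$type == "Feature") {
    co <- g$geometry$coordinates
    ty <- g$geometry$type
  } else {
    co <- g$coordinates
    ty <- g$type
  }
  if (is.null(ty) || ty != "Polygon") stop("GeoJSON geometry is not a Polygon")
  if (is.list(co)) {
    if (length(co) > 1) stop("GeoJSON Polygon with holes is not supported")
    co <- co[[1]]
  } else if (length(dim(co)) == 3) {
    if (dim(co)[1] > 1) stop("GeoJSON Polygon with holes is not supported")
    co <- co[1, , ]
  }
  as.matrix(co)
}
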