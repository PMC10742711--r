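#' Marked planar point pattern
#'
#' A collection of exact event locations inside an observation window,
#' optionally carrying one categorical mark per point (e.g. the size class
#' of the animal group that produced the event).
#'
#' @param x,y numeric coordinate vectors of equal length (possibly length 0).
#' @param window a [obs_window()] object containing all points. Points on the
#'   boundary count as inside.
#' @param marks optional vector/factor of categorical marks, one per point.
#' @param check if `TRUE` (default), verify containment of every point.
#' @return An object of class `"spat_ppp"`: list with `x`, `y`, `n`, `marks`
#'   (character or `NULL`), `levels` (declared label set) and `window`.
#' @examples
#' w <- obs_window(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' p <- point_pattern(c(.2, .8), c(.5, .5), w, marks = c("a", "b"))
#' @export
point_pattern <- function(x, y, window, marks = NULL, check = TRUE) {
  stopifnot(inherits(window, "spat_window"))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (anyNA(x) || anyNA(y)) stop("point coordinates contain NA")
  lev <- NULL
  if (!is.null(marks)) {
    if (length(marks) != length(x)) stop("marks length differs from n")
    lev <- if (is.factor(marks)) levels(marks) else unique(as.character(marks))
    marks <- as.character(marks)
  }
  if (check && length(x) > 0) {
    ok <- points_in_window(window, x, y)
    if (!all(ok)) {
      stop(sum(!ok), " point(s) fall outside the observation window")
    }
  }
  structure(list(x = x, y = y, n = length(x), marks = marks,
                 levels = lev, window = window),
            class = "spat_ppp")
}

#' @export
print.spat_ppp <- function(x, ...) {
  cat("Point pattern:", x$n, "points")
  if (!is.null(x$marks)) cat(",", length(x$levels), "mark levels")
  cat(", window area", format(x$window$area), "\n")
  invisible(x)
}

#' Read a point pattern from CSV plus a window file
#'
#' The CSV must have a header with numeric `x` and `y` columns; any further
#' columns may hold categorical marks. The window file is WKT or GeoJSON
#' (see [read_window()]).
#'
#' @param points_file path to the CSV of coordinates.
#' @param window_file path to the polygon window file.
#' @param mark_column optional name of the mark column to attach.
#' @param drop_outside if `FALSE` (default) any point outside the window is an
#'   error; if `TRUE`, outside points are dropped with a message reporting
#'   how many.
#' @return A [point_pattern()] object.
#' @export
read_point_pattern <- function(points_file, window_file, mark_column = NULL,
                               drop_outside = FALSE) {
  if (!file.exists(points_file)) stop("points file not found: ", points_file)
  df <- read.csv(points_file, stringsAsFactors = FALSE)
  if (nrow(df) > 0 && (!all(c("x", "y") %in% names(df)) ||
                       !is.numeric(df$x) || !is.numeric(df$y))) {
    stop("points CSV must have numeric 'x' and 'y' columns")
  }
  win <- read_window(window_file)
  x <- if (nrow(df)) df$x else numeric(0)
  y <- if (nrow(df)) df$y else numeric(0)
  marks <- NULL
  if (!is.null(mark_column)) {
    if (!mark_column %in% names(df)) {
      stop("mark column '", mark_column, "' not present in ", points_file)
    }
    marks <- as.character(df[[mark_column]])
  }
  if (length(x) > 0) {
    ok <- points_in_window(win, x, y)
    if (!all(ok)) {
      if (!drop_outside) {
        stop(sum(!ok), " point(s) outside the window; ",
             "use drop_outside = TRUE to discard them")
      }
      message("dropping ", sum(!ok), " point(s) outside the window")
      x <- x[ok]; y <- y[ok]
      if (!is.null(marks)) marks <- marks[ok]
    }
  }
  point_pattern(x, y, win, marks = marks, check = FALSE)
}

#' Nearest-neighbour and pairwise distance summaries
#'
#' The two standard interpoint-distance distributions used to choose the
#' co-occurrence distance `d`: per-point nearest-neighbour distances and all
#' pairwise distances, with their quantiles.
#'
#' @param pattern a [point_pattern()] with at least 2 points.
#' @return list with `nn_distances` (length n), `pairwise_distances`
#'   (length n(n-1)/2), and `nn_quantiles`, `pairwise_quantiles` (deciles,
#'   type-7).
#' @export
distance_summaries <- function(pattern) {
  stopifnot(inherits(pattern, "spat_ppp"))
  if (pattern$n < 2) stop("distance summaries need at least 2 points")
  dm <- as.matrix(dist(cbind(pattern$x, pattern$y)))
  diag(dm) <- Inf
  nn <- apply(dm, 1, min)
  pw <- dm[upper.tri(dm)]
  q <- seq(0, 1, by = 0.1)
  list(nn_distances = unname(nn),
       pairwise_distances = pw,
       nn_quantiles = quantile(nn, q, type = 7),
       pairwise_quantiles = quantile(pw, q, type = 7))
}
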