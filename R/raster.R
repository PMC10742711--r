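#' Gridded raster with a NODATA mask
#'
#' A rectangular grid of values (categorical labels or numeric covariate
#' values) over cells of physical size `xstep` x `ystep`. Cells are half-open
#' rectangles `[x_lo, x_hi) x [y_lo, y_hi)`; row 1 is the southernmost row;
#' the centroid of cell `(r, c)` is
#' `(x0 + (c - 0.5) * xstep, y0 + (r - 0.5) * ystep)`. `NA` values mark
#' NODATA cells (e.g. outside an irregular window); no entropy computation
#' ever reads them.
#'
#' @param values a matrix (row 1 = southernmost row). Character/factor for
#'   categorical rasters, numeric for continuous covariates.
#' @param x0,y0 coordinates of the lower-left corner of the grid.
#' @param xstep,ystep positive cell widths (coordinate units).
#' @return An object of class `"spat_raster"`.
#' @examples
#' r <- spat_raster(matrix(c("a", "b", "b", "a"), 2, 2))
#' @export
spat_raster <- function(values, x0 = 0, y0 = 0, xstep = 1, ystep = 1) {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (is.factor(values)) values <- matrix(as.character(values), nrow(values))
  if (xstep <= 0 || ystep <= 0) stop("cell sizes must be positive")
  structure(list(values = values, nrows = nrow(values), ncols = ncol(values),
                 x0 = as.numeric(x0), y0 = as.numeric(y0),
                 xstep = as.numeric(xstep), ystep = as.numeric(ystep)),
            class = "spat_raster")
}

#' @export
print.spat_raster <- function(x, ...) {
  cat("Raster:", x$nrows, "x", x$ncols, "cells of",
      format(x$xstep), "x", format(x$ystep), "units;",
      sum(is.na(x$values)), "NODATA\n")
  invisible(x)
}

#' Centroids and values of the valid (non-NODATA) cells
#' @param raster a [spat_raster()].
#' @return data.frame with `x`, `y`, `value`, `row`, `col`.
#' @export
valid_cells <- function(raster) {
  stopifnot(inherits(raster, "spat_raster"))
  idx <- which(!is.na(raster$values), arr.ind = TRUE)
  data.frame(
    x = raster$x0 + (idx[, "col"] - 0.5) * raster$xstep,
    y = raster$y0 + (idx[, "row"] - 0.5) * raster$ystep,
    value = raster$values[idx],
    row = idx[, "row"], col = idx[, "col"],
    stringsAsFactors = FALSE
  )
}

#' Read an ESRI ASCII grid
#'
#' Standard `.asc` header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, optional `NODATA_value`) followed by `nrows` rows of values,
#' northernmost row first. A documented extension supports rectangular
#' cells: the `cellsize` line may be replaced by two lines `dx` and `dy`.
#'
#' @param path file path.
#' @param categorical if `TRUE` (default) values are kept as character
#'   labels; if `FALSE` they are converted to numeric.
#' @return A [spat_raster()].
#' @export
read_ascii_grid <- function(path, categorical = TRUE) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr_keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                "dx", "dy", "nodata_value")
  hdr <- list(); i <- 1
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2 && tolower(parts[1]) %in% hdr_keys) {
      hdr[[tolower(parts[1])]] <- parts[2]
      i <- i + 1
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner")
  if (!all(need %in% names(hdr))) {
    stop("malformed ESRI ASCII header: missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  }
  if (!is.null(hdr$cellsize)) {
    dx <- dy <- as.numeric(hdr$cellsize)
  } else if (!is.null(hdr$dx) && !is.null(hdr$dy)) {
    dx <- as.numeric(hdr$dx); dy <- as.numeric(hdr$dy)
  } else {
    stop("malformed ESRI ASCII header: need cellsize, or dx and dy")
  }
  nodata <- hdr$nodata_value
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+"))
  body <- body[nzchar(body)]
  if (length(body) != nr * nc) {
    stop("ESRI ASCII body has ", length(body), " values, expected ", nr * nc)
  }
  # file order: northernmost row first -> flip so row 1 is southernmost
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)[nr:1, , drop = FALSE]
  if (!is.null(nodata)) m[m == nodata] <- NA
  if (!categorical) {
    m2 <- suppressWarnings(matrix(as.numeric(m), nr, nc))
    if (any(is.na(m2) & !is.na(m))) stop("non-numeric values in numeric raster")
    m <- m2
  }
  spat_raster(m, x0 = as.numeric(hdr$xllcorner), y0 = as.numeric(hdr$yllcorner),
              xstep = dx, ystep = dy)
}

#' Write an ESRI ASCII grid
#'
#' Emits the standard `cellsize` header for square cells and the `dx`/`dy`
#' two-line extension only when `xstep != ystep`.
#'
#' @param raster a [spat_raster()].
#' @param path output file path.
#' @param nodata value written for `NA` cells (default `-9999`).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path, nodata = "-9999") {
  stopifnot(inherits(raster, "spat_raster"))
  hdr <- c(paste("ncols", raster$ncols), paste("nrows", raster$nrows),
           paste("xllcorner", format(raster$x0, scientific = FALSE)),
           paste("yllcorner", format(raster$y0, scientific = FALSE)))
  hdr <- c(hdr, if (raster$xstep == raster$ystep) {
    paste("cellsize", format(raster$xstep, scientific = FALSE))
  } else {
    c(paste("dx", format(raster$xstep, scientific = FALSE)),
      paste("dy", format(raster$ystep, scientific = FALSE)))
  })
  hdr <- c(hdr, paste("NODATA_value", nodata))
  m <- raster$values
  m[is.na(m)] <- nodata
  rows <- apply(m[raster$nrows:1, , drop = FALSE], 1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Convert a point pattern to a binary presence/absence raster
#'
#' Overlays an `nrows` x `ncols` grid on the window's bounding box and labels
#' each cell `"1"` (presence) if at least one point falls in it, `"0"`
#' otherwise; multiple points in a cell collapse to a single presence. Cells
#' whose centroid lies outside the window polygon are masked NODATA. Cells
#' are half-open, so a point on a shared edge belongs to the higher-index
#' cell (points on the outermost top/right edge go to the last cell).
#'
#' @param pattern a [point_pattern()].
#' @param nrows,ncols grid dimensions (>= 1).
#' @return A binary [spat_raster()] with labels `"0"`/`"1"` and NODATA
#'   outside the window.
#' @export
pixellate_pattern <- function(pattern, nrows, ncols) {
  stopifnot(inherits(pattern, "spat_ppp"))
  nrows <- as.integer(nrows); ncols <- as.integer(ncols)
  if (nrows < 1 || ncols < 1) stop("grid dimensions must be >= 1")
  bb <- pattern$window$bbox
  if (bb["xmax"] <= bb["xmin"] || bb["ymax"] <= bb["ymin"]) {
    stop("degenerate window bounding box")
  }
  xstep <- (bb["xmax"] - bb["xmin"]) / ncols
  ystep <- (bb["ymax"] - bb["ymin"]) / nrows
  m <- matrix("0", nrows, ncols)
  if (pattern$n > 0) {
    cc <- pmin(floor((pattern$x - bb["xmin"]) / xstep) + 1L, ncols)
    rr <- pmin(floor((pattern$y - bb["ymin"]) / ystep) + 1L, nrows)
    m[cbind(rr, cc)] <- "1"
  }
  ctr <- expand.grid(row = seq_len(nrows), col = seq_len(ncols))
  cx <- bb["xmin"] + (ctr$col - 0.5) * xstep
  cy <- bb["ymin"] + (ctr$row - 0.5) * ystep
  inside <- points_in_window(pattern$window, cx, cy)
  m[cbind(ctr$row, ctr$col)[!inside, , drop = FALSE]] <- NA
  spat_raster(m, x0 = unname(bb["xmin"]), y0 = unname(bb["ymin"]),
              xstep = unname(xstep), ystep = unname(ystep))
}
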