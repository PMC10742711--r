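#' Co-occurrence table of ordered category couples
#'
#' Counts of ordered couples `(a, b)` of categories observed at two related
#' locations — related either by rook contiguity on a grid or by lying
#' within a distance `d`. With `I` base categories there are `I^2` couple
#' types.
#'
#' @param counts an `I x I` matrix of couple counts (rows = first element of
#'   the couple), or a named numeric vector of length `I^2` with names like
#'   `"a-b"` laid out row-wise.
#' @param categories character vector of the `I` base category labels
#'   (required when `counts` is an unnamed vector).
#' @param rule list describing the pairing rule, e.g.
#'   `list(type = "contiguity")` or `list(type = "distance", d = 500)`.
#' @return An object of class `"cooccurrence_table"`: list with
#'   `categories`, `counts` (I x I matrix), `probs`, `total_pairs`, `rule`.
#' @examples
#' cooccurrence_table(matrix(c(39775, 919, 919, 179), 2, byrow = TRUE),
#'                    categories = c("0", "1"))
#' @export
cooccurrence_table <- function(counts, categories = NULL,
                               rule = list(type = "contiguity")) {
  if (!is.matrix(counts)) {
    I <- as.integer(sqrt(length(counts)))
    if (I * I != length(counts)) stop("counts must have length I^2")
    if (is.null(categories) && !is.null(names(counts))) {
      categories <- unique(sub("-.*$", "", names(counts)))
    }
    counts <- matrix(as.numeric(counts), I, I, byrow = TRUE)
  }
  I <- nrow(counts)
  if (ncol(counts) != I) stop("counts must be a square matrix")
  if (is.null(categories)) categories <- as.character(seq_len(I))
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("co-occurrence table has no pairs")
  dimnames(counts) <- list(categories, categories)
  structure(list(categories = as.character(categories), counts = counts,
                 probs = counts / total, total_pairs = total, rule = rule),
            class = "cooccurrence_table")
}

#' @export
print.cooccurrence_table <- function(x, ...) {
  cat("Co-occurrence table (", x$rule$type, "): ",
      length(x$categories), " categories, ", format(x$total_pairs),
      " pairs\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Couple table as a flat data frame
#' @param table a `"cooccurrence_table"`.
#' @return data.frame with `couple`, `count`, `prob` rows in row-wise order.
#' @export
couple_frequencies <- function(table) {
  stopifnot(inherits(table, "cooccurrence_table"))
  cats <- table$categories
  lab <- as.vector(t(outer(cats, cats, paste, sep = "-")))
  data.frame(couple = lab,
             count = as.vector(t(table$counts)),
             prob = as.vector(t(table$probs)),
             stringsAsFactors = FALSE)
}

#' Symmetrise a co-occurrence table
#'
#' Splits each mixed ordered count equally between `a-b` and `b-a`, leaving
#' the total and the probabilities' sum unchanged.
#'
#' @param table a `"cooccurrence_table"`.
#' @return A symmetrised `"cooccurrence_table"`.
#' @export
symmetrise_table <- function(table) {
  stopifnot(inherits(table, "cooccurrence_table"))
  m <- (table$counts + t(table$counts)) / 2
  cooccurrence_table(m, categories = table$categories, rule = table$rule)
}

#' Contiguous (rook-adjacent) couples of a categorical raster
#'
#' Enumerates every pair of valid cells sharing an edge exactly once by
#' scanning each cell's east and north neighbour, and records the ordered
#' couple (scan-origin category, neighbour category). Pairs touching a
#' NODATA cell are skipped.
#'
#' @param raster a categorical [spat_raster()] with at least one adjacency
#'   between valid cells.
#' @param symmetrise split mixed ordered counts equally between the two
#'   orders (default `FALSE`).
#' @return A `"cooccurrence_table"` with `rule = list(type = "contiguity")`.
#' @export
contiguous_couples <- function(raster, symmetrise = FALSE) {
  stopifnot(inherits(raster, "spat_raster"))
  v <- raster$values
  labs <- unique(v[!is.na(v)])
  if (length(labs) == 0) stop("raster has no valid cells")
  I <- length(labs)
  f <- matrix(match(v, labs), nrow(v), ncol(v))
  acc <- matrix(0, I, I)
  tally <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return()
    t2 <- table(factor(a[ok], levels = seq_len(I)),
                factor(b[ok], levels = seq_len(I)))
    acc <<- acc + unclass(t2)
  }
  nr <- nrow(f); nc <- ncol(f)
  if (nc > 1) tally(f[, -nc], f[, -1])   # east neighbour
  if (nr > 1) tally(f[-1, ], f[-nr, ])   # south neighbour (row 1 = south)
  if (sum(acc) == 0) stop("no adjacencies between valid cells")
  tab <- cooccurrence_table(acc, categories = as.character(labs),
                            rule = list(type = "contiguity"))
  if (symmetrise) symmetrise_table(tab) else tab
}

.coerce_cooc <- function(x, need = "any") {
  if (inherits(x, "cooccurrence_table")) return(x)
  if (inherits(x, "spat_raster")) return(contiguous_couples(x))
  stop("expected a cooccurrence_table or a categorical raster")
}

#' O'Neill's contiguity entropy
#'
#' Shannon entropy of the ordered contiguous-couple distribution,
#' `H_O = sum_r p(z_r) log(1 / p(z_r))`, in `[0, log I^2]`; the relative
#' value is `H_O / log I^2`. Low values mean adjacent cells tend to form
#' homogeneous couples.
#'
#' @param x a `"cooccurrence_table"` (any rule) or a categorical
#'   [spat_raster()] (contiguous couples are built first).
#' @return An `"entropy_result"`.
#' @examples
#' oneill_entropy(cooccurrence_table(c(39775, 919, 919, 179),
#'                                   categories = c("0", "1")))
#' @export
oneill_entropy <- function(x) {
  tab <- .coerce_cooc(x)
  I <- length(tab$categories)
  H <- .plogp(as.vector(tab$probs))
  hmax <- log(I^2)
  entropy_result("O'Neill", value = H, range = c(0, hmax),
                 relative = if (I == 1) 0 else H / hmax,
                 table = tab,
                 meta = list(I = I, total_pairs = tab$total_pairs))
}

#' Relative contagion index
#'
#' `1 - H_O^rel`: high when adjacent cells tend to share categories
#' (strong "contagion"), zero when all couple types are equally frequent.
#'
#' @inheritParams oneill_entropy
#' @return An `"entropy_result"` with `value = relative` in `[0, 1]`.
#' @export
contagion <- function(x) {
  o <- oneill_entropy(x)
  entropy_result("Relative contagion", value = 1 - o$relative,
                 range = c(0, 1), relative = 1 - o$relative,
                 table = o$table, meta = o$meta)
}

#' Parresol and Edwards' entropy
#'
#' The negative of O'Neill's entropy, `-H_O`; its relative value coincides
#' with O'Neill's relative entropy.
#'
#' @inheritParams oneill_entropy
#' @return An `"entropy_result"` with `value = -H_O`.
#' @export
parresol_edwards <- function(x) {
  o <- oneill_entropy(x)
  entropy_result("Parresol-Edwards", value = -o$value,
                 range = c(-o$range[2], 0), relative = o$relative,
                 table = o$table, meta = o$meta)
}

# locations + categories from pattern-with-marks or categorical raster,
# in canonical order (ascending x, then y, then input order)
.pair_basis <- function(data) {
  if (inherits(data, "spat_ppp")) {
    if (is.null(data$marks)) stop("distance couples need a marked pattern")
    x <- data$x; y <- data$y; cat <- data$marks
  } else if (inherits(data, "spat_raster")) {
    vc <- valid_cells(data)
    x <- vc$x; y <- vc$y; cat <- as.character(vc$value)
  } else stop("expected a marked point pattern or a categorical raster")
  ord <- order(x, y, seq_along(x))
  list(x = x[ord], y = y[ord], cat = cat[ord], labs = unique(cat[ord]))
}

#' Couples of observations within a distance
#'
#' Enumerates each unordered pair of observations at Euclidean distance
#' `<= d` exactly once — iterating `i` over the canonical order (ascending
#' x, then y, then input order) and `j` over later elements — and records
#' the ordered couple `(category_i, category_j)`. For rasters, observations
#' are the valid-cell centroids in physical units.
#'
#' @param data a marked [point_pattern()] or a categorical [spat_raster()].
#' @param d inclusive distance threshold (> 0).
#' @param symmetrise split mixed ordered counts equally (default `FALSE`).
#' @return A `"cooccurrence_table"` with
#'   `rule = list(type = "distance", d = d)`; errors (reporting the minimum
#'   interpoint distance) if no pair lies within `d`.
#' @export
distance_couples <- function(data, d, symmetrise = FALSE) {
  if (d <= 0) stop("d must be positive")
  b <- .pair_basis(data)
  n <- length(b$x)
  if (n < 2) stop("need at least 2 observations")
  I <- length(b$labs)
  f <- match(b$cat, b$labs)
  acc <- matrix(0, I, I)
  mind <- Inf
  block <- max(64L, min(1024L, as.integer(4e6 / n)))
  for (i0 in seq(1L, n - 1L, by = block)) {
    i1 <- min(i0 + block - 1L, n - 1L)
    ii <- i0:i1
    jj <- (i0 + 1L):n
    dx <- outer(b$x[ii], b$x[jj], "-")
    dy <- outer(b$y[ii], b$y[jj], "-")
    dd <- sqrt(dx^2 + dy^2)
    keep <- which(dd <= d & (row(dd) + i0 - 1L) < (col(dd) + i0), arr.ind = TRUE)
    upper <- (row(dd) + i0 - 1L) < (col(dd) + i0)
    if (any(upper)) mind <- min(mind, min(dd[upper]))
    if (nrow(keep)) {
      a <- f[keep[, 1] + i0 - 1L]
      bcat <- f[keep[, 2] + i0]
      t2 <- table(factor(a, levels = seq_len(I)),
                  factor(bcat, levels = seq_len(I)))
      acc <- acc + unclass(t2)
    }
  }
  if (sum(acc) == 0) {
    stop("no pair within d = ", d, "; minimum interpoint distance is ",
         format(mind))
  }
  tab <- cooccurrence_table(acc, categories = b$labs,
                            rule = list(type = "distance", d = d,
                                        data_kind = if (inherits(data, "spat_ppp"))
                                          "points" else "grid"))
  if (symmetrise) symmetrise_table(tab) else tab
}

#' Leibovici's distance-based entropy
#'
#' Shannon entropy of the couple distribution at distance `d`,
#' `H_L = sum_r p_d(z_r) log(1 / p_d(z_r))`, in `[0, log I^2]`; relative
#' value `H_L / log I^2`. Generalises O'Neill's contiguity to any distance
#' and to point data.
#'
#' @param data a marked [point_pattern()], a categorical [spat_raster()],
#'   or a prebuilt `"cooccurrence_table"`.
#' @param d inclusive distance threshold (ignored when `data` is already a
#'   table).
#' @return An `"entropy_result"`.
#' @export
leibovici_entropy <- function(data, d = NULL) {
  tab <- if (inherits(data, "cooccurrence_table")) data else {
    if (is.null(d)) stop("d is required")
    distance_couples(data, d)
  }
  I <- length(tab$categories)
  H <- .plogp(as.vector(tab$probs))
  hmax <- log(I^2)
  entropy_result("Leibovici", value = H, range = c(0, hmax),
                 relative = if (I == 1) 0 else H / hmax,
                 table = tab,
                 meta = list(I = I, d = tab$rule$d,
                             total_pairs = tab$total_pairs))
}

#' Relative Leibovici entropy across a set of distances
#'
#' @param data a marked [point_pattern()] or categorical [spat_raster()].
#' @param d_list numeric vector of distances.
#' @return data.frame with `d`, `relative`, `total_pairs`; distances with no
#'   pair are reported with `NA` values.
#' @export
distance_sweep <- function(data, d_list) {
  rows <- lapply(d_list, function(d) {
    res <- tryCatch(leibovici_entropy(data, d), error = function(e) NULL)
    if (is.null(res)) {
      data.frame(d = d, relative = NA_real_, total_pairs = NA_real_)
    } else {
      data.frame(d = d, relative = res$relative,
                 total_pairs = res$meta$total_pairs)
    }
  })
  do.call(rbind, rows)
}
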