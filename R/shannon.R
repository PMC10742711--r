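#' Entropy result container
#'
#' All measures in the package return an `"entropy_result"`: the entropy
#' `value` in nats, its theoretical `range`, the `relative` value under the
#' measure's documented normalisation, the frequency `table` the value was
#' computed from, and a `meta` list naming the measure and its parameters.
#'
#' @keywords internal
entropy_result <- function(measure, value, range, relative, table, meta = list()) {
  structure(list(measure = measure, value = value,
                 range = range, relative = relative,
                 table = table, meta = meta, unit = "nats"),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(x$measure, " entropy: ", sprintf("%.2f", x$value), " nats, range [",
      sprintf("%.2f", x$range[1]), ", ", sprintf("%.2f", x$range[2]),
      "], relative ", sprintf("%.2f", x$relative), "\n", sep = "")
  invisible(x)
}

# sum of p*log(1/p) with the 0*log(1/0) := 0 continuity convention
.plogp <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Tabulate category frequencies
#'
#' Counts and relative frequencies of the categorical outcomes in a mark
#' vector, a point pattern's marks, or a raster's valid cells. Label order
#' is first appearance, stable.
#'
#' @param x a [point_pattern()] with marks, a [spat_raster()], or a plain
#'   vector/factor of category labels.
#' @return A `"category_distribution"`: data.frame with `label`, `count`,
#'   `prob`.
#' @examples
#' tabulate_categories(c("a", "a", "b"))
#' @export
tabulate_categories <- function(x) {
  if (inherits(x, "spat_ppp")) {
    if (is.null(x$marks)) stop("point pattern has no marks to tabulate")
    v <- x$marks
  } else if (inherits(x, "spat_raster")) {
    v <- x$values[!is.na(x$values)]
  } else {
    v <- as.character(x)
    v <- v[!is.na(v)]
  }
  if (length(v) == 0) stop("no observations to tabulate")
  labs <- unique(v)
  counts <- as.integer(table(factor(v, levels = labs)))
  structure(data.frame(label = labs, count = counts,
                       prob = counts / sum(counts),
                       stringsAsFactors = FALSE),
            class = c("category_distribution", "data.frame"))
}

#' Build a category distribution from known counts
#'
#' Convenience constructor for desk-scale computations where the category
#' counts are already tabulated (e.g. from a published frequency table).
#'
#' @param counts non-negative integer vector, optionally named.
#' @param labels optional category labels (defaults to names or 1..I).
#' @return A `"category_distribution"`.
#' @export
category_distribution <- function(counts, labels = NULL) {
  if (is.null(labels)) {
    labels <- if (!is.null(names(counts))) names(counts) else
      as.character(seq_along(counts))
  }
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("at least one observation is required")
  structure(data.frame(label = as.character(labels), count = counts,
                       prob = counts / sum(counts),
                       stringsAsFactors = FALSE),
            class = c("category_distribution", "data.frame"))
}

#' Shannon's entropy
#'
#' `H(X) = sum_i p_i log(1/p_i)` in nats, with probabilities estimated by
#' the plug-in relative frequencies `n_i/n`; zero-count categories
#' contribute zero. The range is `[0, log I]` and the relative entropy is
#' `H / log I` (defined as 1 when `I = 1`). Shannon's entropy is invariant
#' to any spatial rearrangement of the observations: it sees only the
#' frequency vector.
#'
#' @param x a `"category_distribution"`, or anything accepted by
#'   [tabulate_categories()] (marked pattern, raster, label vector).
#' @return An `"entropy_result"`.
#' @examples
#' shannon_entropy(category_distribution(c(350, 297)))
#' @export
shannon_entropy <- function(x) {
  tab <- if (inherits(x, "category_distribution")) x else tabulate_categories(x)
  I <- nrow(tab)
  H <- .plogp(tab$prob)
  hmax <- log(I)
  entropy_result("Shannon", value = H, range = c(0, hmax),
                 relative = if (I == 1) 1 else H / hmax,
                 table = tab, meta = list(I = I, n = sum(tab$count)))
}
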