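# Point sets on the pixel grid and pointwise grid metrics.

#' Construct a point set
#'
#' A point set is a two-column integer matrix of 0-based `(row, col)`
#' coordinates with duplicates removed.
#'
#' @param points A two-column matrix (or coercible) of coordinates.
#' @return A `pointset`: a two-column integer matrix, possibly with 0 rows.
#' @export
as_pointset <- function(points) {
  if (is.null(points) || length(points) == 0L) {
    m <- matrix(integer(0), ncol = 2)
  } else {
    m <- as.matrix(points)
    if (ncol(m) != 2L) {
      stop_bmkfo("a pointset needs two coordinate columns",
                 class = "bmkfo_invalid_argument")
    }
    m <- unique(m)
    storage.mode(m) <- "integer"
  }
  colnames(m) <- c("row", "col")
  structure(m, class = c("pointset", class(m)))
}

#' Distance between two grid points
#'
#' @param x,y Length-2 finite numeric coordinate vectors `(row, col)`.
#' @param metric One of `"manhattan"` (L1), `"euclidean"` (L2) or
#'   `"chebyshev"` (L-infinity; distance measurable in all grid directions,
#'   the default metric of the Hausdorff losses in this package).
#' @return A nonnegative scalar; zero iff `x == y`; symmetric in `x, y`.
#' @examples
#' point_distance(c(0, 0), c(3, 4), "euclidean") # 5
#' @export
point_distance <- function(x, y, metric = c("chebyshev", "manhattan", "euclidean")) {
  metric <- match_metric(match.arg(metric))
  if (length(x) != 2L || length(y) != 2L || !all(is.finite(c(x, y)))) {
    stop_bmkfo("coordinates must be finite length-2 vectors",
               class = "bmkfo_invalid_argument")
  }
  d <- abs(x - y)
  switch(metric,
         manhattan = sum(d),
         euclidean = sqrt(sum(d^2)),
         chebyshev = max(d))
}

# All pairwise distances between two point sets (n x m matrix).
pairwise_distances <- function(X, Y, metric) {
  dr <- abs(outer(X[, 1], Y[, 1], "-"))
  dc <- abs(outer(X[, 2], Y[, 2], "-"))
  switch(metric,
         manhattan = dr + dc,
         euclidean = sqrt(dr^2 + dc^2),
         chebyshev = pmax(dr, dc))
}

#' Extract the point set of a binary mask
#'
#' @param mask A binary 0/1 matrix.
#' @param mode `"foreground"`: all pixels equal to 1 (default mode of the
#'   losses). `"boundary"`: foreground pixels with at least one background
#'   4-neighbor, the image border counting as background.
#' @return A [as_pointset()] with 0-based coordinates; empty for an all-zero
#'   mask (callers of the distance operations must handle that case).
#' @export
mask_to_pointset <- function(mask, mode = c("foreground", "boundary")) {
  mode <- match.arg(mode)
  assert_binary_mask(mask)
  idx <- which(mask == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(as_pointset(NULL))
  if (mode == "boundary") {
    h <- nrow(mask); w <- ncol(mask)
    padded <- matrix(0, h + 2, w + 2)
    padded[2:(h + 1), 2:(w + 1)] <- mask
    i <- idx[, 1] + 1L; j <- idx[, 2] + 1L
    interior <- padded[cbind(i - 1L, j)] == 1 & padded[cbind(i + 1L, j)] == 1 &
      padded[cbind(i, j - 1L)] == 1 & padded[cbind(i, j + 1L)] == 1
    idx <- idx[!interior, , drop = FALSE]
  }
  as_pointset(idx - 1L)
}

check_nonempty_set <- function(X, name) {
  if (!is.matrix(X) || nrow(X) == 0L) {
    stop_bmkfo("point set '", name, "' is empty; all-background masks must be ",
               "handled before computing set distances",
               class = "bmkfo_empty_set")
  }
  invisible(X)
}
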