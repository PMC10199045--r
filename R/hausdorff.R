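# Exact set-based Hausdorff distances, exact distance transforms, the
# differentiable average-Hausdorff surrogate, cross-entropy, and the combined
# training objective.

#' Directed Hausdorff distance from X to Y
#'
#' `max` over points of `X` of the minimum distance to `Y`. Not symmetric in
#' general; a subset has zero forward distance to its superset.
#'
#' @param X,Y Non-empty point sets ([as_pointset()] or two-column matrices).
#' @inheritParams point_distance
#' @return A nonnegative scalar.
#' @export
directed_hd <- function(X, Y, metric = c("chebyshev", "manhattan", "euclidean")) {
  metric <- match_metric(match.arg(metric))
  X <- as_pointset(X); Y <- as_pointset(Y)
  check_nonempty_set(X, "X"); check_nonempty_set(Y, "Y")
  D <- pairwise_distances(X, Y, metric)
  max(do.call(pmin, as.data.frame(D)))
}

#' Symmetric Hausdorff distance
#'
#' The maximum of the two directed distances. Symmetric; zero iff the sets
#' are equal; sensitive to single outlier points (one stray prediction pixel
#' moves the value to its full distance), which is the weakness the average
#' form addresses.
#'
#' @inheritParams directed_hd
#' @param pred,gt Non-empty point sets (prediction and ground truth).
#' @return A nonnegative scalar.
#' @export
hd_loss <- function(pred, gt, metric = c("chebyshev", "manhattan", "euclidean")) {
  metric <- match.arg(metric)
  max(directed_hd(pred, gt, metric), directed_hd(gt, pred, metric))
}

#' Average Hausdorff distance between two point sets
#'
#' Mean over `X` of the minimum distance to `Y`, plus the mean over `Y` of
#' the minimum distance to `X`, divided by two. Symmetric, never larger than
#' [hd_loss()] on the same sets, zero iff the sets coincide, and robust to
#' single outliers (one stray point among `n` perturbs the value by about
#' `d/(2n)` rather than jumping to `d`).
#'
#' @inheritParams directed_hd
#' @return A nonnegative scalar.
#' @export
ahd <- function(X, Y, metric = c("chebyshev", "manhattan", "euclidean")) {
  metric <- match_metric(match.arg(metric))
  X <- as_pointset(X); Y <- as_pointset(Y)
  check_nonempty_set(X, "X"); check_nonempty_set(Y, "Y")
  D <- pairwise_distances(X, Y, metric)
  fwd <- mean(do.call(pmin, as.data.frame(D)))
  bwd <- mean(do.call(pmin, as.data.frame(t(D))))
  (fwd + bwd) / 2
}

#' Exact distance transform of a binary mask
#'
#' Grid of the minimum distance from every pixel to the reference point set
#' of `gt` (foreground pixels by default, boundary pixels optionally). Exact
#' under all three metrics: two-pass chamfer propagation with the
#' 4-neighborhood (Manhattan) or 8-neighborhood (Chebyshev), and the
#' lower-envelope-of-parabolas algorithm on squared distances (Euclidean).
#'
#' @param gt A binary mask with at least one reference pixel.
#' @inheritParams point_distance
#' @param mode Point-set mode passed to [mask_to_pointset()].
#' @return A numeric matrix, same shape as `gt`; zero on the reference set.
#' @export
distance_transform <- function(gt,
                               metric = c("chebyshev", "manhattan", "euclidean"),
                               mode = c("foreground", "boundary")) {
  metric <- match_metric(match.arg(metric))
  mode <- match.arg(mode)
  assert_binary_mask(gt)
  S <- mask_to_pointset(gt, mode)
  check_nonempty_set(S, "gt foreground")
  seed <- matrix(FALSE, nrow(gt), ncol(gt))
  seed[S + 1L] <- TRUE
  switch(metric,
         manhattan = chamfer_dt(seed, diag8 = FALSE),
         chebyshev = chamfer_dt(seed, diag8 = TRUE),
         euclidean = euclidean_dt(seed))
}

# Two-pass chamfer distance transform with unit step costs. With the
# 4-neighborhood this is the exact L1 distance; with the 8-neighborhood the
# exact Chebyshev distance (both metrics are realized by monotone grid paths,
# so one forward and one backward raster scan suffice).
chamfer_dt <- function(seed, diag8) {
  h <- nrow(seed); w <- ncol(seed)
  D <- matrix(Inf, h, w)
  D[seed] <- 0
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      d <- D[i, j]
      if (i > 1 && D[i - 1, j] + 1 < d) d <- D[i - 1, j] + 1
      if (j > 1 && D[i, j - 1] + 1 < d) d <- D[i, j - 1] + 1
      if (diag8) {
        if (i > 1 && j > 1 && D[i - 1, j - 1] + 1 < d) d <- D[i - 1, j - 1] + 1
        if (i > 1 && j < w && D[i - 1, j + 1] + 1 < d) d <- D[i - 1, j + 1] + 1
      }
      D[i, j] <- d
    }
  }
  for (i in rev(seq_len(h))) {
    for (j in rev(seq_len(w))) {
      d <- D[i, j]
      if (i < h && D[i + 1, j] + 1 < d) d <- D[i + 1, j] + 1
      if (j < w && D[i, j + 1] + 1 < d) d <- D[i, j + 1] + 1
      if (diag8) {
        if (i < h && j < w && D[i + 1, j + 1] + 1 < d) d <- D[i + 1, j + 1] + 1
        if (i < h && j > 1 && D[i + 1, j - 1] + 1 < d) d <- D[i + 1, j - 1] + 1
      }
      D[i, j] <- d
    }
  }
  D
}

# Exact 1-D squared-distance transform (lower envelope of parabolas).
dt1d_squared <- function(f) {
  n <- length(f)
  finite <- which(is.finite(f))
  if (length(finite) == 0L) return(rep(Inf, n))
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- finite[1L]
  z[1L] <- -Inf; z[2L] <- Inf
  if (length(finite) > 1L) {
    for (q in finite[-1L]) {
      repeat {
        p <- v[k]
        s <- ((f[q] + q^2) - (f[p] + p^2)) / (2 * q - 2 * p)
        if (s <= z[k]) {
          k <- k - 1L
        } else {
          k <- k + 1L
          v[k] <- q
          z[k] <- s
          z[k + 1L] <- Inf
          break
        }
      }
    }
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

euclidean_dt <- function(seed) {
  h <- nrow(seed); w <- ncol(seed)
  F <- matrix(Inf, h, w)
  F[seed] <- 0
  for (j in seq_len(w)) F[, j] <- dt1d_squared(F[, j])
  for (i in seq_len(h)) F[i, ] <- dt1d_squared(F[i, ])
  sqrt(F)
}

# Counter for ground-truth slices skipped by the average-Hausdorff term.
.bmkfo_counters <- new.env(parent = emptyenv())
.bmkfo_counters$ahd_skipped <- 0L

#' Number of empty-foreground slices skipped by the AHD term so far
#' @return Integer count (process-wide, reset with `reset = TRUE`).
#' @param reset If `TRUE`, reset the counter to zero after reading.
#' @export
ahd_skipped_count <- function(reset = FALSE) {
  n <- .bmkfo_counters$ahd_skipped
  if (reset) .bmkfo_counters$ahd_skipped <- 0L
  n
}

#' Differentiable average-Hausdorff surrogate loss
#'
#' The exact set-based average Hausdorff distance is not differentiable in a
#' probability map (it thresholds and takes min/argmin over sets). This
#' surrogate replaces the two directed means with distance-transform inner
#' products:
#' \deqn{(\langle p, D_{gt}\rangle/\Sigma p + \langle g, D_{pred}\rangle/\Sigma g)/2}
#' where `D_gt` is the exact distance transform of the ground truth, `D_pred`
#' the distance transform of the prediction thresholded at `threshold`, `p`
#' the probability grid and `g` the 0/1 ground truth. When `pred` is exactly
#' binary the value equals the exact foreground-mode [ahd()]. The gradient
#' (returned in attribute `"gradient"`, same shape as `pred`) flows through
#' `p` in the first term only; the thresholded second term is treated as a
#' constant.
#'
#' @param pred A probability map (matrix in `[0, 1]`), same shape as `gt`.
#' @param gt A binary mask with non-empty foreground.
#' @inheritParams point_distance
#' @param threshold Threshold applied to `pred` for the second term
#'   (default 0.5).
#' @return A nonnegative scalar with attribute `"gradient"`. If `sum(pred)`
#'   is zero a configured large constant (the grid diameter under `metric`)
#'   is returned with zero gradient and a degenerate-prediction warning.
#' @export
soft_ahd_loss <- function(pred, gt,
                          metric = c("chebyshev", "manhattan", "euclidean"),
                          threshold = 0.5) {
  metric <- match_metric(match.arg(metric))
  assert_prob_map(pred)
  assert_binary_mask(gt)
  if (!all(dim(pred) == dim(gt))) {
    stop_bmkfo("pred and gt shapes differ: ", paste(dim(pred), collapse = "x"),
               " vs ", paste(dim(gt), collapse = "x"),
               class = "bmkfo_shape_error")
  }
  if (sum(gt) == 0) {
    stop_bmkfo("gt has empty foreground", class = "bmkfo_empty_set")
  }
  big <- grid_diameter(dim(gt), metric)
  S <- sum(pred)
  if (S == 0) {
    warning("degenerate prediction: sum(pred) == 0; returning large constant ",
            "with zero gradient", call. = FALSE)
    out <- big
    attr(out, "gradient") <- matrix(0, nrow(pred), ncol(pred))
    return(out)
  }
  D_gt <- distance_transform(gt, metric)
  term1 <- sum(pred * D_gt) / S
  pred_bin <- (pred >= threshold) * 1
  if (sum(pred_bin) == 0) {
    term2 <- big
  } else {
    D_pred <- distance_transform(pred_bin, metric)
    term2 <- sum(gt * D_pred) / sum(gt)
  }
  out <- (term1 + term2) / 2
  attr(out, "gradient") <- (D_gt - term1) / (2 * S)
  out
}

grid_diameter <- function(dims, metric) {
  point_distance(c(0, 0), c(dims[1] - 1, dims[2] - 1), metric)
}

#' Pixelwise cross-entropy
#'
#' Mean over pixels of `-sum_c y_c log(max(p_c, eps))` for a per-class
#' probability stack and a one-hot ground-truth stack. The probability floor
#' `eps` keeps the value finite at zero predicted probability; it affects the
#' value only where a true class receives probability below `eps`.
#'
#' @param pred An `H x W x C` array of per-class probabilities summing to 1
#'   per pixel (within 1e-6).
#' @param gt An `H x W x C` one-hot 0/1 array.
#' @param eps Probability floor (default `1e-7`).
#' @return A nonnegative scalar.
#' @export
cross_entropy <- function(pred, gt, eps = 1e-7) {
  if (!is.array(pred) || !is.array(gt) || length(dim(pred)) != 3L ||
      !all(dim(pred) == dim(gt))) {
    stop_bmkfo("pred and gt must be H x W x C arrays of equal shape",
               class = "bmkfo_shape_error")
  }
  sums <- apply(pred, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6)) {
    stop_bmkfo("per-pixel class probabilities must sum to 1",
               class = "bmkfo_invalid_argument")
  }
  if (!all(gt %in% c(0, 1))) {
    stop_bmkfo("gt must be one-hot 0/1", class = "bmkfo_invalid_argument")
  }
  npix <- dim(pred)[1] * dim(pred)[2]
  sum(gt * -log(pmax(pred, eps))) / npix
}

#' Combined training objective: cross-entropy plus average-Hausdorff surrogate
#'
#' `w_ce * CE + w_ahd * AHD_surrogate`, the unweighted sum by default. For a
#' ground truth with empty foreground the AHD term is undefined and is
#' skipped (cross-entropy only); the skip is counted, see
#' [ahd_skipped_count()].
#'
#' @param pred An `H x W x 2` probability array; class 2 is foreground.
#' @param gt A binary foreground mask (`H x W`).
#' @param weights Length-2 nonnegative vector `c(ce, ahd)`; default `c(1, 1)`.
#' @inheritParams soft_ahd_loss
#' @return A scalar with attribute `"gradient"`: the derivative with respect
#'   to the foreground probability `pred[ , , 2]` contributed by the AHD term
#'   (the cross-entropy gradient is handled by the network's own backward
#'   pass).
#' @export
total_loss <- function(pred, gt, weights = c(1, 1),
                       metric = c("chebyshev", "manhattan", "euclidean"),
                       threshold = 0.5) {
  metric <- match.arg(metric)
  if (length(weights) != 2L || any(weights < 0) || !all(is.finite(weights))) {
    stop_bmkfo("weights must be two nonnegative numbers",
               class = "bmkfo_invalid_argument")
  }
  assert_binary_mask(gt)
  gt_hot <- array(c(1 - gt, gt), dim = c(dim(gt), 2L))
  ce <- cross_entropy(pred, gt_hot)
  ahd_term <- 0
  grad <- matrix(0, nrow(gt), ncol(gt))
  if (weights[2] > 0) {
    if (sum(gt) == 0) {
      .bmkfo_counters$ahd_skipped <- .bmkfo_counters$ahd_skipped + 1L
    } else {
      s <- soft_ahd_loss(pred[, , 2], gt, metric, threshold)
      ahd_term <- as.numeric(s)
      grad <- weights[2] * attr(s, "gradient")
    }
  }
  out <- weights[1] * ce + weights[2] * ahd_term
  attr(out, "components") <- c(ce = ce, ahd = ahd_term)
  attr(out, "gradient") <- grad
  out
}
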