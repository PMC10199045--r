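# A small conditioned convolutional segmentation network with analytic
# gradients. The network is deliberately model-agnostic from the optimizer's
# point of view: parameters are an ordered named list of matrices, so the
# meta-optimization machinery never inspects the architecture.
#
# Input contract: channels = (target image, mean support image, mean support
# mask); output: per-pixel 2-class logits. Convolutions are stride-1 with
# zero padding, realized as im2col gathers followed by matrix products, which
# keeps every trainable tensor a plain matrix (rows = output channels,
# columns = input channels x kernel area) ready for Kronecker factoring.

#' Specify a conditioned segmentation network
#'
#' @param channels Integer vector of hidden-layer widths (a final 2-channel
#'   logit layer is appended automatically).
#' @param kernel Odd kernel side length (default 3).
#' @param in_channels Input channels; 3 under the episode conditioning
#'   contract (query image, support image, support mask).
#' @param n_classes Output classes (2: background/foreground).
#' @param param_cap Maximum total trainable parameter count.
#' @return A `seg_model_spec` object.
#' @export
seg_model_spec <- function(channels = c(8, 8), kernel = 3, in_channels = 3,
                           n_classes = 2, param_cap = 50000) {
  if (kernel %% 2 != 1) {
    stop_bmkfo("kernel must be odd", class = "bmkfo_invalid_argument")
  }
  widths <- c(in_channels, channels, n_classes)
  n_par <- 0
  for (l in seq_len(length(widths) - 1L)) {
    n_par <- n_par + widths[l + 1] * (widths[l] * kernel^2) + widths[l + 1]
  }
  if (n_par > param_cap) {
    stop_bmkfo("parameter count ", n_par, " exceeds cap ", param_cap,
               class = "bmkfo_invalid_argument")
  }
  structure(list(channels = channels, kernel = as.integer(kernel),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes), n_params = n_par),
            class = "seg_model_spec")
}

#' Initialize model parameters
#'
#' Fan-in-scaled Gaussian weights (`sd = 1/sqrt(fan_in)`), zero biases;
#' deterministic per seed. Biases are stored as `m x 1` matrices so every
#' parameter tensor is a matrix eligible for Kronecker factoring.
#'
#' @param spec A [seg_model_spec()].
#' @param seed Integer seed.
#' @return A named list of matrices (`W1`, `b1`, `W2`, ...).
#' @export
init_params <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "seg_model_spec"))
  widths <- c(spec$in_channels, spec$channels, spec$n_classes)
  with_seed(seed, {
    theta <- list()
    for (l in seq_len(length(widths) - 1L)) {
      fan_in <- widths[l] * spec$kernel^2
      theta[[paste0("W", l)]] <- matrix(
        rnorm(widths[l + 1] * fan_in, 0, 1 / sqrt(fan_in)),
        nrow = widths[l + 1], ncol = fan_in)
      theta[[paste0("b", l)]] <- matrix(0, widths[l + 1], 1)
    }
    theta
  })
}

# im2col gather-index cache: for each (h, w, channels, kernel) the linear
# indices into the zero-padded input that produce the (h*w) x (c*k^2) patch
# matrix. Padding cells point at a sentinel position holding 0.
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(h, w, ch, k) {
  key <- paste(h, w, ch, k, sep = "_")
  cached <- .im2col_cache[[key]]
  if (!is.null(cached)) return(cached)
  p <- (k - 1L) %/% 2L
  hp <- h + 2L * p; wp <- w + 2L * p
  # position (i, j) of the padded grid, channel c, offset (di, dj)
  i <- rep(seq_len(h), times = w)
  j <- rep(seq_len(w), each = h)
  npix <- h * w
  cols <- matrix(0L, npix, ch * k * k)
  col <- 0L
  for (c in seq_len(ch)) {
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        col <- col + 1L
        cols[, col] <- (c - 1L) * hp * wp + (j + dj - 2L) * hp + (i + di - 1L)
      }
    }
  }
  out <- list(idx = cols, hp = hp, wp = wp, p = p)
  .im2col_cache[[key]] <- out
  out
}

pad_input <- function(x, p) {
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- x
  out
}

im2col <- function(x, k) {
  d <- dim(x)
  ix <- im2col_index(d[1], d[2], d[3], k)
  xp <- pad_input(x, ix$p)
  matrix(xp[ix$idx], nrow = d[1] * d[2])
}

col2im <- function(dX, h, w, ch, k) {
  ix <- im2col_index(h, w, ch, k)
  flat <- numeric(ix$hp * ix$wp * ch)
  agg <- rowsum(as.vector(dX), group = as.vector(ix$idx))
  flat[as.integer(rownames(agg))] <- agg
  xp <- array(flat, dim = c(ix$hp, ix$wp, ch))
  p <- ix$p
  xp[(p + 1):(p + h), (p + 1):(p + w), , drop = FALSE]
}

#' Forward pass of the conditioned segmentation network
#'
#' @param spec A [seg_model_spec()].
#' @param theta Parameters from [init_params()] (or adapted copies).
#' @param input An `H x W x in_channels` array (see [episode_input()]).
#' @param keep_cache Keep layer activations for a backward pass.
#' @return An `H x W x n_classes` logit array; with `keep_cache = TRUE`, the
#'   im2col matrices and pre-activations are attached as attribute `"cache"`.
#' @export
seg_forward <- function(spec, theta, input, keep_cache = FALSE) {
  stopifnot(inherits(spec, "seg_model_spec"))
  d <- dim(input)
  if (length(d) != 3L || d[3] != spec$in_channels) {
    stop_bmkfo("input must be H x W x ", spec$in_channels,
               class = "bmkfo_shape_error")
  }
  widths <- c(spec$in_channels, spec$channels, spec$n_classes)
  n_layers <- length(widths) - 1L
  feat <- input
  cache <- if (keep_cache) vector("list", n_layers) else NULL
  Z <- NULL
  for (l in seq_len(n_layers)) {
    W <- theta[[paste0("W", l)]]
    b <- theta[[paste0("b", l)]]
    if (is.null(W) || ncol(W) != widths[l] * spec$kernel^2 ||
        nrow(W) != widths[l + 1]) {
      stop_bmkfo("parameter shape mismatch at layer ", l,
                 class = "bmkfo_shape_error")
    }
    X <- im2col(feat, spec$kernel)
    Z <- X %*% t(W) + matrix(b, nrow(X), length(b), byrow = TRUE)
    if (keep_cache) cache[[l]] <- list(X = X, Z = Z)
    if (l < n_layers) {
      feat <- array(pmax(Z, 0), dim = c(d[1], d[2], widths[l + 1]))
    }
  }
  logits <- array(Z, dim = c(d[1], d[2], spec$n_classes))
  if (keep_cache) attr(logits, "cache") <- cache
  logits
}

# Backward pass: dZ_last is (npix x n_classes); returns gradient list
# matching theta. Biases come back as m x 1 matrices.
seg_backward <- function(spec, theta, input, cache, dZ) {
  d <- dim(input)
  widths <- c(spec$in_channels, spec$channels, spec$n_classes)
  n_layers <- length(widths) - 1L
  grad <- vector("list", 2L * n_layers)
  names(grad) <- names(theta)
  for (l in rev(seq_len(n_layers))) {
    W <- theta[[paste0("W", l)]]
    X <- cache[[l]]$X
    grad[[paste0("W", l)]] <- t(dZ) %*% X
    grad[[paste0("b", l)]] <- matrix(colSums(dZ), ncol = 1)
    if (l > 1L) {
      dX <- dZ %*% W
      dfeat <- col2im(dX, d[1], d[2], widths[l], spec$kernel)
      dA <- matrix(dfeat, nrow = d[1] * d[2])
      dZ <- dA * (cache[[l - 1L]]$Z > 0)
    }
  }
  grad
}

#' Build the conditioned input array of an episode
#'
#' Channels: target image, mean support image, mean support mask. With
#' `role = "support"` the support image itself is the target (the standard
#' 1-shot construction: the only labeled example serves both as exemplar and
#' adaptation target).
#'
#' @param episode An episode from [make_episode()].
#' @param role `"query"` or `"support"`.
#' @param shot Which support example is the target when `role = "support"`.
#' @return A list: `input` (`H x W x 3` array) and `target` (binary mask).
#' @export
episode_input <- function(episode, role = c("query", "support"), shot = 1) {
  role <- match.arg(role)
  s_img <- Reduce(`+`, lapply(episode$support, `[[`, "image")) /
    length(episode$support)
  s_mask <- Reduce(`+`, lapply(episode$support, `[[`, "mask")) /
    length(episode$support)
  if (role == "query") {
    tgt_img <- episode$query$image
    target <- episode$query$mask
  } else {
    tgt_img <- episode$support[[shot]]$image
    target <- episode$support[[shot]]$mask
  }
  input <- array(c(tgt_img, s_img, s_mask), dim = c(dim(tgt_img), 3L))
  list(input = input, target = target)
}

# Softmax over the class dimension of an (npix x 2) logit matrix, numerically
# stable for two classes.
softmax2 <- function(Z) {
  zmax <- pmax(Z[, 1], Z[, 2])
  e1 <- exp(Z[, 1] - zmax); e2 <- exp(Z[, 2] - zmax)
  s <- e1 + e2
  cbind(e1 / s, e2 / s)
}

#' Loss and analytic gradient of the network on one (input, target) pair
#'
#' Combined objective `w_ce * CE + w_ahd * soft-AHD` with the analytic
#' gradient with respect to every parameter tensor. The soft-AHD gradient
#' flows through the foreground probability (first surrogate term) only.
#'
#' @inheritParams seg_forward
#' @param target Binary target mask.
#' @param weights `c(ce, ahd)` loss weights.
#' @param metric,threshold Passed to the AHD surrogate.
#' @param dt_gt Optional precomputed distance transform of `target` (training
#'   caches this per episode).
#' @param eps Cross-entropy probability floor.
#' @return A list: `value`, `grad` (named list matching `theta`),
#'   `components` (`ce`, `ahd`).
#' @export
seg_loss_grad <- function(spec, theta, input, target, weights = c(1, 0),
                          metric = "chebyshev", threshold = 0.5,
                          dt_gt = NULL, eps = 1e-7) {
  d <- dim(input)
  npix <- d[1] * d[2]
  logits <- seg_forward(spec, theta, input, keep_cache = TRUE)
  cache <- attr(logits, "cache")
  Z <- matrix(logits, nrow = npix)
  P <- softmax2(Z)
  y <- as.vector(target)
  p_true <- ifelse(y == 1, P[, 2], P[, 1])
  ce <- mean(-log(pmax(p_true, eps)))
  Y <- cbind(1 - y, y)
  dZ <- weights[1] * (P - Y) / npix
  ahd_val <- 0
  if (weights[2] > 0 && sum(target) > 0) {
    p_fg <- matrix(P[, 2], d[1], d[2])
    if (is.null(dt_gt)) dt_gt <- distance_transform(target, metric)
    S <- sum(p_fg)
    big <- grid_diameter(dim(target), metric)
    if (S == 0) {
      ahd_val <- big
    } else {
      term1 <- sum(p_fg * dt_gt) / S
      pred_bin <- (p_fg >= threshold) * 1
      term2 <- if (sum(pred_bin) == 0) {
        big
      } else {
        sum(target * distance_transform(pred_bin, metric)) / sum(target)
      }
      ahd_val <- (term1 + term2) / 2
      g_p <- (dt_gt - term1) / (2 * S)           # d(surrogate)/d p_fg
      pq <- P[, 1] * P[, 2]                       # softmax Jacobian factor
      dZ[, 2] <- dZ[, 2] + weights[2] * as.vector(g_p) * pq
      dZ[, 1] <- dZ[, 1] - weights[2] * as.vector(g_p) * pq
    }
  }
  value <- weights[1] * ce + weights[2] * ahd_val
  grad <- seg_backward(spec, theta, input, cache, dZ)
  list(value = value, grad = grad, components = c(ce = ce, ahd = ahd_val))
}

#' Predict a binary query mask for an episode
#'
#' @inheritParams seg_forward
#' @param episode An episode.
#' @param threshold Foreground-probability threshold.
#' @return A binary mask; the foreground probability map is attached as
#'   attribute `"prob"`.
#' @export
predict_episode <- function(spec, theta, episode, threshold = 0.5) {
  ei <- episode_input(episode, "query")
  logits <- seg_forward(spec, theta, ei$input)
  P <- softmax2(matrix(logits, ncol = 2))
  prob <- matrix(P[, 2], dim(ei$input)[1], dim(ei$input)[2])
  mask <- (prob >= threshold) * 1
  attr(mask, "prob") <- prob
  mask
}
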