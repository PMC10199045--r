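# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: distances are computed from the raw
# coordinate formulas, set distances by explicit min/max over all pairs, and
# the Kronecker product by the blockwise definition with a double loop.

oracle_point_dist <- function(x, y, metric) {
  d1 <- abs(x[1] - y[1]); d2 <- abs(x[2] - y[2])
  switch(metric,
         manhattan = d1 + d2,
         euclidean = sqrt(d1^2 + d2^2),
         chebyshev = max(d1, d2))
}

# min distance from one point to every row of a set, vectorized on the set
oracle_min_dist <- function(x, S, metric) {
  d1 <- abs(S[, 1] - x[1]); d2 <- abs(S[, 2] - x[2])
  switch(metric,
         manhattan = min(d1 + d2),
         euclidean = min(sqrt(d1^2 + d2^2)),
         chebyshev = min(pmax(d1, d2)))
}

oracle_directed_hd <- function(X, Y, metric) {
  max(vapply(seq_len(nrow(X)), function(i) oracle_min_dist(X[i, ], Y, metric),
             numeric(1)))
}

oracle_hd <- function(X, Y, metric) {
  max(oracle_directed_hd(X, Y, metric), oracle_directed_hd(Y, X, metric))
}

oracle_ahd <- function(X, Y, metric) {
  fwd <- mean(vapply(seq_len(nrow(X)), function(i) {
    oracle_min_dist(X[i, ], Y, metric)
  }, numeric(1)))
  bwd <- mean(vapply(seq_len(nrow(Y)), function(j) {
    oracle_min_dist(Y[j, ], X, metric)
  }, numeric(1)))
  (fwd + bwd) / 2
}

# O(pixels x |set|) distance transform
oracle_dt <- function(mask, metric) {
  S <- which(mask == 1, arr.ind = TRUE) - 1L
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      out[i, j] <- oracle_min_dist(c(i - 1, j - 1), S, metric)
    }
  }
  out
}

# Blockwise Kronecker product straight from the definition
oracle_kron <- function(A, B) {
  m <- nrow(A); n <- ncol(A); p <- nrow(B); q <- ncol(B)
  out <- matrix(0, m * p, n * q)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      out[((i - 1) * p + 1):(i * p), ((j - 1) * q + 1):(j * q)] <- A[i, j] * B
    }
  }
  out
}

random_binary_mask <- function(h, w, p = NULL, nonempty = TRUE) {
  if (is.null(p)) p <- runif(1, 0.05, 0.5)
  repeat {
    m <- matrix(rbinom(h * w, 1, p), h, w)
    if (!nonempty || sum(m) > 0) return(m)
  }
}

# Manhattan-metric Voronoi labels of seed pixels (ties -> lowest seed index)
oracle_voronoi_manhattan <- function(h, w, seeds_rc0) {
  lab <- matrix(NA_integer_, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      d <- abs(seeds_rc0[, 1] - (i - 1)) + abs(seeds_rc0[, 2] - (j - 1))
      lab[i, j] <- which.min(d) # which.min takes the first (lowest index) tie
    }
  }
  lab
}

# independent 4-connectivity component count (BFS with an explicit queue)
oracle_n_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  ncomp <- 0L
  for (start in which(mask == 1 & !seen)) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      i <- (v - 1) %% h + 1; j <- (v - 1) %/% h + 1
      for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
        if (nb[1] >= 1 && nb[1] <= h && nb[2] >= 1 && nb[2] <= w) {
          u <- (nb[2] - 1) * h + nb[1]
          if (mask[u] == 1 && !seen[u]) {
            seen[u] <- TRUE
            queue <- c(queue, u)
          }
        }
      }
    }
  }
  ncomp
}

# quadratic task family: support 0.5 t(x) A x - b.x, query 0.5 t(x) C x - d.x
quadratic_task <- function(A, b, C, d) {
  list(
    support = function(th) list(value = 0.5 * sum(th$W * (A %*% th$W)) - sum(b * th$W),
                                grad = list(W = A %*% th$W - b)),
    query = function(th) list(value = 0.5 * sum(th$W * (C %*% th$W)) - sum(d * th$W),
                              grad = list(W = C %*% th$W - d)))
}

random_spd <- function(n) {
  M <- matrix(rnorm(n * n), n, n)
  crossprod(M) / n + diag(n) * 0.1
}

# tiny high-contrast episode stream for smoke training
tiny_episodes <- function(n, seed = 1, size = 32, classes = default_shape_classes()) {
  lapply(seq_len(n), function(i) {
    cls <- classes[[(i - 1) %% length(classes) + 1]]
    make_episode(cls, size = size, seed = seed * 1000 + i, noise_sd = 0.03,
                 bias = FALSE)
  })
}
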