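# Set-based Hausdorff machinery against brute-force oracles, metric
# dominance, the differentiable surrogate, and the combined objective.

test_that("point_distance matches the coordinate formulas and their ordering", {
  expect_equal(point_distance(c(0, 0), c(3, 4), "manhattan"), 7)
  expect_equal(point_distance(c(0, 0), c(3, 4), "euclidean"), 5)
  expect_equal(point_distance(c(0, 0), c(3, 4), "chebyshev"), 4)
  set.seed(1)
  for (i in 1:200) {
    x <- sample(-20:20, 2); y <- sample(-20:20, 2)
    dm <- point_distance(x, y, "manhattan")
    de <- point_distance(x, y, "euclidean")
    dc <- point_distance(x, y, "chebyshev")
    expect_equal(dm, oracle_point_dist(x, y, "manhattan"))
    expect_equal(de, oracle_point_dist(x, y, "euclidean"))
    expect_equal(dc, oracle_point_dist(x, y, "chebyshev"))
    expect_true(dc <= de + 1e-12 && de <= dm + 1e-12)
    expect_identical(point_distance(x, x, "euclidean"), 0)
  }
  expect_error(point_distance(c(0, 0), c(1, 1), "cosine"))
})

test_that("directed_hd is the max-min distance and is order-sensitive", {
  expect_equal(directed_hd(rbind(c(0, 0)), rbind(c(0, 3), c(4, 0)), "euclidean"), 3)
  A <- rbind(c(0, 0), c(1, 1))
  B <- rbind(c(0, 0), c(1, 1), c(9, 9))
  expect_equal(directed_hd(A, B, "chebyshev"), 0)   # subset -> zero forward
  expect_gt(directed_hd(B, A, "chebyshev"), 0)
  expect_equal(directed_hd(A, A, "manhattan"), 0)
  set.seed(2)
  for (i in 1:20) {
    X <- mask_to_pointset(random_binary_mask(8, 8))
    Y <- mask_to_pointset(random_binary_mask(8, 8))
    for (metric in c("manhattan", "euclidean", "chebyshev")) {
      expect_equal(directed_hd(X, Y, metric), oracle_directed_hd(X, Y, metric))
    }
  }
  expect_error(directed_hd(matrix(integer(0), 0, 2), A, "euclidean"),
               class = "bmkfo_empty_set")
})

test_that("hd_loss is symmetric, zero iff equal, and outlier-sensitive", {
  set.seed(3)
  gt <- mask_to_pointset(random_binary_mask(10, 10, 0.4))
  expect_equal(hd_loss(gt, gt, "chebyshev"), 0)
  # one stray predicted point at chebyshev distance 9 drives the whole loss to 9
  far <- c(max(gt[, 1]) + 9L, max(gt[, 2]) + 9L)
  stopifnot(oracle_min_dist(far, gt, "chebyshev") == 9)
  pred <- as_pointset(rbind(gt, far))
  expect_equal(hd_loss(pred, gt, "chebyshev"), 9)
  for (i in 1:10) {
    X <- mask_to_pointset(random_binary_mask(8, 8))
    Y <- mask_to_pointset(random_binary_mask(8, 8))
    expect_identical(hd_loss(X, Y, "euclidean"), hd_loss(Y, X, "euclidean"))
  }
})

test_that("ahd matches brute force, is symmetric, bounded by hd_loss, and outlier-robust", {
  expect_equal(ahd(rbind(c(0, 0), c(0, 1)), rbind(c(0, 0)), "manhattan"), 0.25)
  set.seed(4)
  for (i in 1:20) {
    X <- mask_to_pointset(random_binary_mask(9, 9))
    Y <- mask_to_pointset(random_binary_mask(9, 9))
    for (metric in c("manhattan", "euclidean", "chebyshev")) {
      a <- ahd(X, Y, metric)
      expect_equal(a, oracle_ahd(X, Y, metric))
      expect_identical(a, ahd(Y, X, metric))
      expect_lte(a, hd_loss(X, Y, metric) + 1e-12)
    }
    # metric dominance transfers from the pointwise distances
    expect_lte(ahd(X, Y, "chebyshev"), ahd(X, Y, "euclidean") + 1e-12)
    expect_lte(ahd(X, Y, "euclidean"), ahd(X, Y, "manhattan") + 1e-12)
  }
  expect_identical(ahd(rbind(c(1, 2)), rbind(c(1, 2)), "euclidean"), 0)
  # one far outlier among 100 points moves ahd by ~ d/200 but hd_loss by d
  base <- as_pointset(as.matrix(expand.grid(0:9, 0:9)))
  d_out <- 50
  X_out <- as_pointset(rbind(base, c(9 + d_out, 9)))
  a0 <- ahd(base, base, "chebyshev")
  a1 <- ahd(X_out, base, "chebyshev")
  h1 <- hd_loss(X_out, base, "chebyshev")
  expect_equal(h1, d_out)
  expect_lt(a1 - a0, d_out / 200 * 1.2)
  expect_equal(a1 - a0, oracle_ahd(X_out, base, "chebyshev"))
})

test_that("mask_to_pointset extracts foreground and 4-neighbor boundaries", {
  m <- matrix(1, 3, 3)
  expect_equal(nrow(mask_to_pointset(m, "boundary")), 8)  # center is interior
  expect_equal(nrow(mask_to_pointset(m, "foreground")), 9)
  single <- matrix(0, 4, 4); single[2, 3] <- 1
  expect_equal(mask_to_pointset(single, "foreground"),
               mask_to_pointset(single, "boundary"))
  expect_equal(nrow(mask_to_pointset(matrix(0, 3, 3))), 0)
})

test_that("distance transforms are exact under all three metrics", {
  m <- matrix(0, 1, 5); m[1, 1] <- 1
  expect_equal(as.vector(distance_transform(m, "chebyshev")), 0:4)
  set.seed(5)
  for (i in 1:12) {
    mask <- random_binary_mask(16, 16)
    for (metric in c("manhattan", "euclidean", "chebyshev")) {
      D <- distance_transform(mask, metric)
      expect_equal(D, oracle_dt(mask, metric))
      expect_true(all(D[mask == 1] == 0))
    }
  }
  expect_error(distance_transform(matrix(0, 4, 4), "euclidean"),
               class = "bmkfo_empty_set")
})

test_that("soft_ahd_loss equals exact ahd on binary predictions and is monotone in confidence", {
  set.seed(6)
  for (i in 1:15) {
    pred <- random_binary_mask(16, 16)
    gt <- random_binary_mask(16, 16)
    s <- soft_ahd_loss(pred, gt, "chebyshev")
    expect_lt(abs(as.numeric(s) -
                    ahd(mask_to_pointset(pred), mask_to_pointset(gt), "chebyshev")),
              1e-9)
  }
  gt <- matrix(0, 8, 8); gt[3:5, 3:5] <- 1
  expect_equal(as.numeric(soft_ahd_loss(gt, gt, "euclidean")), 0)
  # moving probability mass toward the foreground strictly decreases term 1
  p0 <- matrix(0.5, 8, 8)
  vals <- vapply(c(0, 0.2, 0.4), function(t) {
    p <- (1 - t) * p0 + t * gt
    as.numeric(soft_ahd_loss(p, gt, "chebyshev"))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  # gradient direction agrees with finite differences away from the threshold
  p <- matrix(runif(64, 0.05, 0.45), 8, 8)
  s <- soft_ahd_loss(p, gt, "chebyshev")
  g <- attr(s, "gradient")
  for (idx in c(1, 20, 40)) {
    e <- 1e-6
    pp <- p; pp[idx] <- pp[idx] + e
    pm <- p; pm[idx] <- pm[idx] - e
    fd <- (as.numeric(soft_ahd_loss(pp, gt, "chebyshev")) -
             as.numeric(soft_ahd_loss(pm, gt, "chebyshev"))) / (2 * e)
    expect_lt(abs(fd - g[idx]), 1e-6)
  }
  expect_warning(out <- soft_ahd_loss(matrix(0, 4, 4), matrix(1, 4, 4)),
                 "degenerate")
  expect_equal(as.numeric(out), point_distance(c(0, 0), c(3, 3), "chebyshev"))
  expect_true(all(attr(out, "gradient") == 0))
})

test_that("cross_entropy matches closed forms and direct summation", {
  gt <- matrix(c(1, 0, 0, 1), 2, 2)
  hot <- array(c(1 - gt, gt), dim = c(2, 2, 2))
  perfect <- hot
  expect_lte(cross_entropy(perfect, hot), -log(1 - 1e-7) + 1e-12)
  uniform <- array(0.5, dim = c(2, 2, 2))
  expect_equal(cross_entropy(uniform, hot), log(2))
  set.seed(7)
  p1 <- matrix(runif(16, 0.01, 0.99), 4, 4)
  pred <- array(c(1 - p1, p1), dim = c(4, 4, 2))
  g <- matrix(rbinom(16, 1, 0.5), 4, 4)
  ghot <- array(c(1 - g, g), dim = c(4, 4, 2))
  direct <- mean(-(g * log(p1) + (1 - g) * log(1 - p1)))
  expect_equal(cross_entropy(pred, ghot), direct)
  bad <- array(0.7, dim = c(2, 2, 2))
  expect_error(cross_entropy(bad, hot), class = "bmkfo_invalid_argument")
})

test_that("total_loss reduces to its parts and is additive in the weights", {
  set.seed(8)
  gt <- matrix(0, 8, 8); gt[2:4, 2:5] <- 1
  p1 <- matrix(runif(64, 0.05, 0.95), 8, 8)
  pred <- array(c(1 - p1, p1), dim = c(8, 8, 2))
  ce_only <- total_loss(pred, gt, weights = c(1, 0))
  ahd_only <- total_loss(pred, gt, weights = c(0, 1))
  both <- total_loss(pred, gt, weights = c(1, 1))
  hot <- array(c(1 - gt, gt), dim = c(8, 8, 2))
  expect_equal(as.numeric(ce_only), cross_entropy(pred, hot))
  expect_equal(as.numeric(ahd_only), as.numeric(soft_ahd_loss(p1, gt)))
  expect_equal(as.numeric(both), as.numeric(ce_only) + as.numeric(ahd_only))
  expect_error(total_loss(pred, gt, weights = c(-1, 1)),
               class = "bmkfo_invalid_argument")
  # empty-foreground ground truth: AHD skipped and counted, CE still computed
  n0 <- ahd_skipped_count(reset = TRUE)
  empty <- matrix(0, 8, 8)
  v <- total_loss(pred, empty, weights = c(1, 1))
  expect_equal(as.numeric(v),
               cross_entropy(pred, array(c(1 - empty, empty), dim = c(8, 8, 2))))
  expect_equal(ahd_skipped_count(), 1L)
})
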