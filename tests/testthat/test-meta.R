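# Meta-optimization: learned update directions, functional inner adaptation,
# MAML against closed forms, the bidirectional step's phase structure, and
# checkpoint round-trips.

test_that("meta_update_direction recovers gradients at identity and matches the vec-oracle", {
  set.seed(1)
  grads <- list(W = matrix(rnorm(12), 3, 4), b = matrix(rnorm(3), 3, 1),
                s = matrix(rnorm(1), 1, 1))
  xi <- identity_optim_params(grads)
  expect_identical(meta_update_direction(grads, xi), grads)
  zero <- lapply(grads, function(g) 0 * g)
  expect_equal(meta_update_direction(zero, xi), zero)
  # random factors: per-tensor equality with the materialized Kronecker map
  xi$W <- factor_pair(matrix(rnorm(9), 3, 3), matrix(rnorm(16), 4, 4))
  out <- meta_update_direction(grads, xi)
  want <- oracle_kron(t(xi$W$right), xi$W$left) %*% as.vector(grads$W)
  expect_lt(max(abs(as.vector(out$W) - want)), 1e-10)
  expect_error(meta_update_direction(grads, xi[c("W", "b")]),
               class = "bmkfo_configuration_error")
})

test_that("inner_adapt is functional and matches the quadratic closed form", {
  set.seed(2)
  c0 <- matrix(rnorm(4), 2, 2)
  loss <- function(th) list(value = 0.5 * sum((th$W - c0)^2),
                            grad = list(W = th$W - c0))
  theta <- list(W = matrix(rnorm(4), 2, 2))
  snapshot <- unserialize(serialize(theta, NULL))
  expect_equal(inner_adapt(theta, loss, alpha = 0, steps = 3),
               theta, ignore_attr = TRUE)
  one <- inner_adapt(theta, loss, alpha = 0.3, steps = 1)
  expect_equal(one$W, theta$W - 0.3 * (theta$W - c0))
  two_direct <- inner_adapt(theta, loss, alpha = 0.3, steps = 2)
  two_composed <- inner_adapt(inner_adapt(theta, loss, 0.3, 1), loss, 0.3, 1)
  expect_equal(two_direct$W, two_composed$W)
  expect_identical(theta, snapshot)  # starting point never mutated
  bad <- function(th) list(value = NaN, grad = list(W = 0 * th$W))
  expect_error(inner_adapt(theta, bad, 0.1, 1), class = "bmkfo_nonfinite")
})

test_that("maml_outer_step matches the hand-derived nested-quadratic gradient", {
  set.seed(3)
  A <- random_spd(3); b <- rnorm(3)
  C <- random_spd(3); d <- rnorm(3)
  task <- quadratic_task(A, b, C, d)
  theta0 <- matrix(rnorm(3), 3, 1)
  alpha <- 0.07; beta <- 0.03
  st <- meta_state(list(W = theta0),
                   hyper = hyper_config(alpha = alpha, beta = beta))
  st2 <- maml_outer_step(st, list(task))
  tp <- theta0 - alpha * (A %*% theta0 - b)
  ref2 <- theta0 - beta * ((diag(3) - alpha * A) %*% (C %*% tp - d))
  expect_lt(max(abs(st2$theta$W - ref2)), 1e-8)
  # first-order approximation deviates by exactly the Hessian term
  st$hyper$second_order <- FALSE
  st1 <- maml_outer_step(st, list(task))
  ref1 <- theta0 - beta * (C %*% tp - d)
  expect_lt(max(abs(st1$theta$W - ref1)), 1e-12)
  hessian_term <- beta * alpha * A %*% (C %*% tp - d)
  expect_lt(max(abs((st2$theta$W - st1$theta$W) - hessian_term)), 1e-8)
  # beta = 0 leaves parameters untouched but advances the counter
  st0 <- meta_state(list(W = theta0), hyper = hyper_config(alpha = alpha, beta = 0))
  stz <- maml_outer_step(st0, list(task))
  expect_identical(stz$theta$W, theta0)
  expect_equal(stz$iter, 1L)
})

test_that("bmkfo with frozen identity factors walks the two-inner-step MAML trajectory", {
  set.seed(4)
  A <- random_spd(2); b <- rnorm(2)
  C <- random_spd(2); d <- rnorm(2)
  task <- quadratic_task(A, b, C, d)
  theta0 <- matrix(rnorm(2), 2, 1)
  ab <- 0.05 # shared step size makes the phase structure comparable
  stb <- meta_state(list(W = theta0),
                    hyper = hyper_config(alpha = ab, beta = ab))
  stm <- meta_state(list(W = theta0),
                    hyper = hyper_config(alpha = ab, beta = ab, inner_steps = 2))
  for (i in 1:3) {
    stb <- bmkfo_step(stb, list(task), freeze_xi = TRUE)
    stm <- maml_outer_step(stm, list(task))
    expect_lt(max(abs(stb$theta$W - stm$theta$W)), 1e-8)
  }
  # alpha = beta = 0: state unchanged apart from the counter
  st0 <- meta_state(list(W = theta0), hyper = hyper_config(alpha = 0, beta = 0))
  stz <- bmkfo_step(st0, list(task))
  expect_identical(stz$theta$W, theta0)
  expect_identical(stz$xi$W$left, st0$xi$W$left)
})

test_that("the meta-test phase at identity factors is exactly one gradient-descent step", {
  set.seed(5)
  A <- random_spd(3); b <- rnorm(3)
  C <- random_spd(3); d <- rnorm(3)
  base <- quadratic_task(A, b, C, d)
  seen <- new.env()
  task <- list(support = base$support,
               query = function(th) {
                 seen$theta_star <- th$W
                 base$query(th)
               })
  theta0 <- matrix(rnorm(3), 3, 1)
  alpha <- 0.04; beta <- 0.02
  st <- meta_state(list(W = theta0),
                   hyper = hyper_config(alpha = alpha, beta = beta))
  invisible(bmkfo_step(st, list(task), freeze_xi = TRUE))
  theta_p <- theta0 - beta * (A %*% theta0 - b)
  ref <- theta_p - alpha * (A %*% theta_p - b)
  expect_lt(max(abs(seen$theta_star - ref)), 1e-10)
})

test_that("the learned scalar factor moves toward the optimal preconditioner", {
  # single-parameter quadratics with curvature c: the optimal preconditioned
  # step alpha * xi equals 1/c, so xi should move above 1 when alpha < 1/c
  set.seed(6)
  alpha <- 0.05; curv <- 4 # optimal effective step 0.25 > alpha
  st <- meta_state(list(W = matrix(0.5, 1, 1)),
                   hyper = hyper_config(alpha = alpha, beta = 0.02))
  for (i in 1:300) {
    tgt <- rnorm(1)
    tk <- list(
      support = function(th) list(value = 0.5 * curv * (th$W[1] - tgt)^2,
                                  grad = list(W = matrix(curv * (th$W[1] - tgt), 1, 1))),
      query = function(th) list(value = 0.5 * curv * (th$W[1] - tgt)^2,
                                grad = list(W = matrix(curv * (th$W[1] - tgt), 1, 1))))
    st <- bmkfo_step(st, list(tk))
  }
  xi_eff <- as.numeric(st$xi$W$left) * as.numeric(st$xi$W$right)
  expect_gt(xi_eff, 1.5) # moved decisively in the predicted direction
})

test_that("metakfo at identity factors reproduces one-step MAML", {
  set.seed(7)
  A <- random_spd(2); b <- rnorm(2)
  C <- random_spd(2); d <- rnorm(2)
  task <- quadratic_task(A, b, C, d)
  theta0 <- matrix(rnorm(2), 2, 1)
  hy <- hyper_config(alpha = 0.06, beta = 0.03)
  stk <- metakfo_step(meta_state(list(W = theta0), hyper = hy), list(task))
  stm <- maml_outer_step(meta_state(list(W = theta0), hyper = hy), list(task))
  expect_lt(max(abs(stk$theta$W - stm$theta$W)), 1e-10)
  # ... and its xi moves when the preconditioner can help
  expect_false(identical(stk$xi$W$left, diag(1)))
})

test_that("checkpoints round-trip exactly and validate structure", {
  set.seed(8)
  spec <- seg_model_spec(channels = c(4))
  theta <- init_params(spec, 1)
  st <- meta_state(theta, hyper = hyper_config(alpha = 0.1, beta = 0.05),
                   model_spec = spec)
  p1 <- withr::local_tempfile(fileext = ".rds")
  p2 <- withr::local_tempfile(fileext = ".rds")
  checkpoint_save(st, p1)
  st_loaded <- checkpoint_load(p1)
  checkpoint_save(st_loaded, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_identical(st_loaded$theta, st$theta)
  other <- meta_state(init_params(seg_model_spec(channels = c(4, 4)), 1))
  expect_error(checkpoint_load(p1, template = other),
               class = "bmkfo_checkpoint_error")
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1, 2), bad)
  expect_error(checkpoint_load(bad), class = "bmkfo_checkpoint_error")
})

test_that("resuming from a checkpoint reproduces the uninterrupted loss trace", {
  spec <- seg_model_spec(channels = c(4))
  episodes <- tiny_episodes(8, seed = 3, size = 16)
  hy <- hyper_config(alpha = 0.1, beta = 0.05, second_order = FALSE)
  full <- train_meta(spec, episodes, hyper = hy, method = "bmkfo", seed = 5)
  half <- train_meta(spec, episodes[1:4], hyper = hy, method = "bmkfo", seed = 5)
  p <- withr::local_tempfile(fileext = ".rds")
  checkpoint_save(half, p)
  resumed <- train_meta(spec, episodes[5:8], hyper = hy, method = "bmkfo",
                        seed = 5, state = checkpoint_load(p))
  expect_equal(resumed$theta, full$theta, tolerance = 1e-12)
  expect_equal(attr(resumed, "log")$total, attr(full, "log")$total[5:8],
               tolerance = 1e-12)
  expect_equal(resumed$iter, full$iter)
})
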