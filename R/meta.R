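# Meta-optimization: MAML with exact second-order outer gradients, the
# Kronecker-factored learned optimizer U_xi, and the bidirectional step that
# updates model and optimizer parameters jointly.
#
# A "task" here is any object providing support/query loss closures over a
# named list of parameter matrices:
#   task$support(theta) -> list(value, grad)
#   task$query(theta)   -> list(value, grad)
# Episodes become tasks via episode_task(); toy analytic tasks (quadratics)
# plug into the same machinery, which is what makes the closed-form oracle
# tests possible.

#' Hyperparameter configuration for meta-training
#'
#' @param alpha Inner/adaptation step size (> 0).
#' @param beta Meta step size (> 0); the reference schedule is 0.001 with a
#'   stepping decay of 0.98 every 1000 outer iterations.
#' @param inner_steps Gradient steps of inner adaptation (>= 1).
#' @param tasks_per_meta_batch Tasks averaged per outer update.
#' @param second_order Differentiate through the inner updates (default);
#'   `FALSE` selects the cheaper first-order approximation.
#' @param lr_decay Multiplicative decay factor applied to `beta`.
#' @param decay_every Outer iterations between decay steps.
#' @param clip Maximum global norm of the outer model-parameter gradient
#'   (`Inf` disables clipping). Losses whose gradient scale varies strongly
#'   across prediction regimes — the average-Hausdorff surrogate scales with
#'   the reciprocal of the predicted foreground mass — need bounded outer
#'   updates to keep the meta-initialization from being catapulted by a few
#'   degenerate episodes.
#' @return A `hyper_config` object.
#' @export
hyper_config <- function(alpha = 0.01, beta = 0.001, inner_steps = 1,
                         tasks_per_meta_batch = 1, second_order = TRUE,
                         lr_decay = 0.98, decay_every = 1000, clip = Inf) {
  if (alpha < 0 || beta < 0) {
    stop_bmkfo("alpha and beta must be nonnegative",
               class = "bmkfo_invalid_argument")
  }
  if (inner_steps < 1) {
    stop_bmkfo("inner_steps must be >= 1", class = "bmkfo_invalid_argument")
  }
  structure(list(alpha = alpha, beta = beta,
                 inner_steps = as.integer(inner_steps),
                 tasks_per_meta_batch = as.integer(tasks_per_meta_batch),
                 second_order = isTRUE(second_order),
                 lr_decay = lr_decay, decay_every = as.integer(decay_every),
                 clip = clip),
            class = "hyper_config")
}

clip_params <- function(g, clip) {
  if (!is.finite(clip)) return(g)
  n <- params_norm(g)
  if (n > clip) params_scale(clip / n, g) else g
}

current_beta <- function(hyper, iter) {
  hyper$beta * hyper$lr_decay^(iter %/% hyper$decay_every)
}

#' Identity optimizer parameters for a parameter list
#'
#' One Kronecker [factor_pair()] per parameter tensor, initialized to the
#' identity so the optimizer starts as plain gradient descent. Tensors with
#' fewer than 4 elements get scalar (1 x 1) factors acting as a single
#' multiplier.
#'
#' @param theta Named list of parameter matrices.
#' @return Named list of `factor_pair` objects (class `optim_params`).
#' @export
identity_optim_params <- function(theta) {
  out <- lapply(theta, function(m) {
    if (length(m) < 4L) {
      identity_factors(1, 1)
    } else {
      identity_factors(nrow(m), ncol(m))
    }
  })
  structure(out, class = "optim_params")
}

is_scalar_pair <- function(F, m) {
  all(F$shape_tag == c(1L, 1L)) && length(m) < 4L
}

#' Transform gradients with the learned Kronecker-factored optimizer
#'
#' Applies `U_xi` tensor-by-tensor: `L %*% G %*% R` for matrix factors,
#' `l * r * G` for scalar factors. With identity factors the output equals
#' the raw gradients, recovering plain gradient descent.
#'
#' @param grads Named list of gradient matrices.
#' @param xi Optimizer parameters from [identity_optim_params()].
#' @return Named list of update directions, same shapes as `grads`.
#' @export
meta_update_direction <- function(grads, xi) {
  out <- grads
  for (nm in names(grads)) {
    F <- xi[[nm]]
    if (is.null(F)) {
      stop_bmkfo("no factor pair configured for parameter tensor '", nm, "'",
                 class = "bmkfo_configuration_error")
    }
    out[[nm]] <- if (is_scalar_pair(F, grads[[nm]])) {
      as.numeric(F$left) * as.numeric(F$right) * grads[[nm]]
    } else {
      apply_factored(grads[[nm]], F, name = nm)
    }
  }
  out
}

# Transpose action of U_xi (needed by the second-order backward pass).
meta_update_direction_t <- function(v, xi) {
  out <- v
  for (nm in names(v)) {
    F <- xi[[nm]]
    out[[nm]] <- if (is_scalar_pair(F, v[[nm]])) {
      as.numeric(F$left) * as.numeric(F$right) * v[[nm]]
    } else {
      apply_factored_t(v[[nm]], F)
    }
  }
  out
}

# Gradient of loss(theta - alpha * U_xi(G)) with respect to the factors,
# given Ghat = grad of the loss at the displaced point and G the gradient the
# optimizer transformed. Closed form per tensor:
#   d/dL = -alpha * Ghat %*% t(G %*% R),  d/dR = -alpha * t(L %*% G) %*% Ghat
# Scalar factors reduce to inner products.
xi_gradient <- function(xi, G, Ghat, alpha) {
  out <- xi
  for (nm in names(xi)) {
    F <- xi[[nm]]
    g <- G[[nm]]; gh <- Ghat[[nm]]
    if (is_scalar_pair(F, g)) {
      ip <- sum(gh * g)
      dl <- -alpha * as.numeric(F$right) * ip
      dr <- -alpha * as.numeric(F$left) * ip
      out[[nm]] <- list(left = matrix(dl, 1, 1), right = matrix(dr, 1, 1))
    } else {
      out[[nm]] <- list(
        left = -alpha * gh %*% t(g %*% F$right),
        right = -alpha * t(F$left %*% g) %*% gh)
    }
  }
  out
}

xi_axpy <- function(a, dxi, xi) {
  out <- xi
  for (nm in names(xi)) {
    out[[nm]] <- factor_pair(xi[[nm]]$left + a * dxi[[nm]]$left,
                             xi[[nm]]$right + a * dxi[[nm]]$right,
                             xi[[nm]]$shape_tag)
  }
  out
}

xi_gradient_zero <- function(xi) {
  lapply(xi, function(F) list(left = 0 * F$left, right = 0 * F$right))
}

xi_gradient_add <- function(acc, g, w = 1) {
  for (nm in names(acc)) {
    acc[[nm]]$left <- acc[[nm]]$left + w * g[[nm]]$left
    acc[[nm]]$right <- acc[[nm]]$right + w * g[[nm]]$right
  }
  acc
}

xi_gradient_clip <- function(g, clip) {
  if (!is.finite(clip)) return(g)
  n <- sqrt(sum(vapply(g, function(f) sum(f$left^2) + sum(f$right^2),
                       numeric(1))))
  if (n <= clip) return(g)
  lapply(g, function(f) list(left = f$left * clip / n,
                             right = f$right * clip / n))
}

check_finite_loss <- function(value, phase, iter = NA) {
  if (!is.finite(value)) {
    stop_bmkfo("non-finite loss (", value, ") in phase '", phase,
               "' at iteration ", iter,
               class = "bmkfo_nonfinite")
  }
  value
}

# Hessian-vector product of a loss closure by central finite differences of
# its analytic gradient. Exact (to rounding) for quadratic losses; for smooth
# losses the error is O(eps^2).
loss_hvp <- function(loss_fn, theta, v, eps_scale = 1e-5) {
  nv <- params_norm(v)
  if (nv == 0) return(params_scale(0, v))
  eps <- eps_scale * (1 + params_norm(theta)) / nv
  gp <- loss_fn(params_axpy(eps, v, theta))$grad
  gm <- loss_fn(params_axpy(-eps, v, theta))$grad
  out <- v
  for (nm in names(v)) out[[nm]] <- (gp[[nm]] - gm[[nm]]) / (2 * eps)
  out
}

#' Inner-loop adaptation by (preconditioned) gradient descent
#'
#' Runs `steps` updates `theta <- theta - alpha * U_xi(grad)` of the given
#' loss, starting from `theta` (which is never modified: adaptation is
#' functional). With `xi = NULL` the update is plain gradient descent.
#'
#' @param theta Named list of parameter matrices.
#' @param loss_fn Closure `function(theta) list(value, grad)`.
#' @param alpha Step size (0 returns `theta` unchanged).
#' @param steps Number of updates.
#' @param xi Optional optimizer parameters.
#' @return Adapted parameters; attribute `"trajectory"` holds the visited
#'   parameter lists (length `steps`, starting point first) and attribute
#'   `"losses"` the loss values along the way.
#' @export
inner_adapt <- function(theta, loss_fn, alpha, steps = 1, xi = NULL) {
  traj <- vector("list", steps)
  losses <- numeric(steps)
  cur <- theta
  for (s in seq_len(steps)) {
    traj[[s]] <- cur
    lg <- loss_fn(cur)
    check_finite_loss(lg$value, "inner-adapt", s)
    losses[s] <- lg$value
    dir <- if (is.null(xi)) lg$grad else meta_update_direction(lg$grad, xi)
    cur <- params_axpy(-alpha, dir, cur)
  }
  attr(cur, "trajectory") <- traj
  attr(cur, "losses") <- losses
  cur
}

#' Construct a meta-learning state
#'
#' @param theta Model parameters.
#' @param xi Optimizer parameters (defaults to identity factors).
#' @param hyper A [hyper_config()].
#' @param seed Root RNG seed recorded with the state.
#' @param model_spec Optional [seg_model_spec()] carried for checkpointing.
#' @return A `meta_state` with an iteration counter starting at 0.
#' @export
meta_state <- function(theta, xi = identity_optim_params(theta),
                       hyper = hyper_config(), seed = 1, model_spec = NULL) {
  structure(list(theta = theta, xi = xi, hyper = hyper, iter = 0L,
                 seed = as.integer(seed), model_spec = model_spec,
                 rng_state = NULL, schema = 1L),
            class = "meta_state")
}

#' One MAML outer step
#'
#' Adapts `theta` to each task by `inner_steps` gradient-descent updates on
#' the support loss, then updates the meta-initial parameters with the
#' query-loss gradient averaged over the batch. By default the outer gradient
#' is exact second-order: the backward pass multiplies the adapted query
#' gradient by the transposed inner-update Jacobians
#' `(I - alpha * H_support)` via Hessian-vector products. The first-order
#' approximation (`second_order = FALSE`) skips those terms.
#'
#' @param state A [meta_state()].
#' @param tasks Non-empty list of tasks (see [episode_task()]).
#' @return The updated `meta_state` (iteration counter advanced).
#' @export
maml_outer_step <- function(state, tasks) {
  stopifnot(inherits(state, "meta_state"), length(tasks) > 0)
  h <- state$hyper
  beta_t <- current_beta(h, state$iter)
  acc <- params_scale(0, state$theta)
  for (task in tasks) {
    adapted <- inner_adapt(state$theta, task$support, h$alpha, h$inner_steps)
    traj <- attr(adapted, "trajectory")
    q <- task$query(adapted)
    check_finite_loss(q$value, "outer", state$iter)
    u <- q$grad
    if (h$second_order && h$alpha > 0) {
      for (k in rev(seq_along(traj))) {
        u <- params_axpy(-h$alpha, loss_hvp(task$support, traj[[k]], u), u)
      }
    }
    acc <- params_axpy(1 / length(tasks), u, acc)
  }
  state$theta <- params_axpy(-beta_t, clip_params(acc, h$clip), state$theta)
  state$iter <- state$iter + 1L
  state
}

#' One bidirectional meta-Kronecker-factored optimizer step
#'
#' Per task, with current meta step size `beta_t`:
#'
#' 1. **Meta-train phase** (support set): `theta' <- theta - beta_t * g0`
#'    with `g0` the support gradient; the optimizer parameters take a
#'    gradient step `xi' <- xi - beta_t * dL/dxi`, where `dL/dxi` is defined
#'    through the probe update `theta~ = theta - alpha * U_xi(g0)` (the raw
#'    support loss does not depend on `xi`; the only well-defined dependence
#'    passes through a `U_xi`-driven update).
#' 2. **Meta-test phase** (support set): `theta* <- theta' -
#'    alpha * U_xi'(grad_support(theta'))`. With identity factors this is
#'    exactly one plain gradient-descent step — the identity-span property.
#' 3. **Outer update** (query set): the query loss at `theta*` is
#'    differentiated with respect to the outer `(theta, xi)` and both are
#'    updated with step `beta_t`, averaged over the batch. Second-order mode
#'    backpropagates through both phases of the `theta` path (Hessian-vector
#'    products) and through `xi'` in the meta-test update; the Jacobian of
#'    the meta-train `xi` update itself is truncated to the identity (its
#'    correction terms carry an extra factor `beta_t`).
#'
#' @param state A [meta_state()].
#' @param tasks Non-empty list of tasks providing support and query closures.
#' @param freeze_xi If `TRUE`, `xi` is neither probed nor updated (used by
#'   equivalence tests against MAML trajectories).
#' @return The updated `meta_state`.
#' @export
bmkfo_step <- function(state, tasks, freeze_xi = FALSE) {
  stopifnot(inherits(state, "meta_state"), length(tasks) > 0)
  h <- state$hyper
  beta_t <- current_beta(h, state$iter)
  acc_theta <- params_scale(0, state$theta)
  acc_xi <- xi_gradient_zero(state$xi)
  w <- 1 / length(tasks)
  for (task in tasks) {
    ## meta-train phase (support set)
    s0 <- task$support(state$theta)
    check_finite_loss(s0$value, "meta-train", state$iter)
    theta_p <- params_axpy(-beta_t, s0$grad, state$theta)
    xi_p <- state$xi
    if (!freeze_xi) {
      probe <- params_axpy(-h$alpha, meta_update_direction(s0$grad, state$xi),
                           state$theta)
      sp <- task$support(probe)
      check_finite_loss(sp$value, "meta-train", state$iter)
      k_xi <- xi_gradient(state$xi, s0$grad, sp$grad, h$alpha)
      xi_p <- xi_axpy(-beta_t, k_xi, state$xi)
    }
    ## meta-test phase (support set)
    s1 <- task$support(theta_p)
    check_finite_loss(s1$value, "meta-test", state$iter)
    theta_star <- params_axpy(-h$alpha, meta_update_direction(s1$grad, xi_p),
                              theta_p)
    ## outer update (query set)
    q <- task$query(theta_star)
    check_finite_loss(q$value, "outer", state$iter)
    u <- q$grad
    if (h$second_order) {
      wt <- meta_update_direction_t(u, xi_p)
      v1 <- if (h$alpha > 0) {
        params_axpy(-h$alpha, loss_hvp(task$support, theta_p, wt), u)
      } else {
        u
      }
      g_theta <- if (beta_t > 0) {
        params_axpy(-beta_t, loss_hvp(task$support, state$theta, v1), v1)
      } else {
        v1
      }
    } else {
      g_theta <- u
    }
    acc_theta <- params_axpy(w, g_theta, acc_theta)
    if (!freeze_xi) {
      acc_xi <- xi_gradient_add(acc_xi, xi_gradient(xi_p, s1$grad, u, h$alpha), w)
    }
  }
  state$theta <- params_axpy(-beta_t, clip_params(acc_theta, h$clip), state$theta)
  if (!freeze_xi) {
    state$xi <- xi_axpy(-beta_t, xi_gradient_clip(acc_xi, h$clip), state$xi)
  }
  state$iter <- state$iter + 1L
  state
}

#' One step of the (unidirectional) Kronecker-factored meta-optimizer
#'
#' The inner update is `theta' <- theta - alpha * U_xi(g_support)`; the outer
#' update differentiates the query loss at `theta'` with respect to both
#' `theta` (second-order by default) and the factors of `xi`, and steps both
#' with the meta step size.
#'
#' @inheritParams bmkfo_step
#' @return The updated `meta_state`.
#' @export
metakfo_step <- function(state, tasks) {
  stopifnot(inherits(state, "meta_state"), length(tasks) > 0)
  h <- state$hyper
  beta_t <- current_beta(h, state$iter)
  acc_theta <- params_scale(0, state$theta)
  acc_xi <- xi_gradient_zero(state$xi)
  w <- 1 / length(tasks)
  for (task in tasks) {
    s0 <- task$support(state$theta)
    check_finite_loss(s0$value, "inner", state$iter)
    theta_p <- params_axpy(-h$alpha, meta_update_direction(s0$grad, state$xi),
                           state$theta)
    q <- task$query(theta_p)
    check_finite_loss(q$value, "outer", state$iter)
    u <- q$grad
    g_theta <- if (h$second_order && h$alpha > 0) {
      wt <- meta_update_direction_t(u, state$xi)
      params_axpy(-h$alpha, loss_hvp(task$support, state$theta, wt), u)
    } else {
      u
    }
    acc_theta <- params_axpy(w, g_theta, acc_theta)
    acc_xi <- xi_gradient_add(acc_xi, xi_gradient(state$xi, s0$grad, u, h$alpha), w)
  }
  state$theta <- params_axpy(-beta_t, clip_params(acc_theta, h$clip), state$theta)
  state$xi <- xi_axpy(-beta_t, xi_gradient_clip(acc_xi, h$clip), state$xi)
  state$iter <- state$iter + 1L
  state
}

#' Save / load a meta-state checkpoint
#'
#' Single-file container (schema-versioned) restoring `theta`, `xi`,
#' hyperparameters, the iteration counter and the RNG state exactly:
#' save-load-save produces identical bytes.
#'
#' @param state A `meta_state`.
#' @param path File path.
#' @return `checkpoint_save` returns `path` invisibly; `checkpoint_load`
#'   returns the restored `meta_state`.
#' @export
checkpoint_save <- function(state, path) {
  stopifnot(inherits(state, "meta_state"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    state$rng_state <- get(".Random.seed", envir = globalenv())
  }
  saveRDS(state, path, compress = FALSE)
  invisible(path)
}

#' @rdname checkpoint_save
#' @param template Optional `meta_state` whose parameter structure the loaded
#'   checkpoint must match (names and shapes).
#' @export
checkpoint_load <- function(path, template = NULL) {
  state <- tryCatch(readRDS(path), error = function(e) {
    stop_bmkfo("corrupt checkpoint at ", path, ": ", conditionMessage(e),
               class = "bmkfo_checkpoint_error")
  })
  if (!inherits(state, "meta_state") || is.null(state$schema)) {
    stop_bmkfo("file is not a meta_state checkpoint",
               class = "bmkfo_checkpoint_error")
  }
  if (state$schema != 1L) {
    stop_bmkfo("checkpoint schema version ", state$schema,
               " not supported (expected 1)", class = "bmkfo_checkpoint_error")
  }
  if (!is.null(template)) {
    same <- identical(names(state$theta), names(template$theta)) &&
      all(mapply(function(a, b) identical(dim(a), dim(b)),
                 state$theta, template$theta))
    if (!same) {
      stop_bmkfo("checkpoint model structure does not match the template",
                 class = "bmkfo_checkpoint_error")
    }
  }
  if (!is.null(state$rng_state)) {
    assign(".Random.seed", state$rng_state, envir = globalenv())
  }
  state
}

#' Wrap an episode as a meta-learning task
#'
#' Support closure: predict the support mask from the support-conditioned
#' input; query closure: predict the query mask. Ground-truth distance
#' transforms are precomputed once per episode.
#'
#' @param spec A [seg_model_spec()].
#' @param episode An episode.
#' @param weights `c(ce, ahd)` loss weights for the query (outer) loss.
#' @param metric,threshold AHD surrogate settings.
#' @param support_weights Loss weights for the support (adaptation) loss;
#'   defaults to `weights`. Keeping the support loss cross-entropy-only while
#'   the outer objective carries the shape term confines the strongly scaled
#'   AHD gradient to the meta-update, where it shapes the initialization
#'   rather than destabilizing the few-step adaptation.
#' @return A task: list of `support` and `query` closures plus the episode.
#' @export
episode_task <- function(spec, episode, weights = c(1, 0),
                         metric = "chebyshev", threshold = 0.5,
                         support_weights = weights) {
  s <- episode_input(episode, "support")
  q <- episode_input(episode, "query")
  dt_s <- if (support_weights[2] > 0 && sum(s$target) > 0) {
    distance_transform(s$target, metric)
  } else {
    NULL
  }
  dt_q <- if (weights[2] > 0 && sum(q$target) > 0) {
    distance_transform(q$target, metric)
  } else {
    NULL
  }
  list(
    support = function(theta) {
      seg_loss_grad(spec, theta, s$input, s$target, support_weights, metric,
                    threshold, dt_gt = dt_s)
    },
    query = function(theta) {
      seg_loss_grad(spec, theta, q$input, q$target, weights, metric,
                    threshold, dt_gt = dt_q)
    },
    episode = episode)
}
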