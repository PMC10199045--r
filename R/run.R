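# Run configuration, dataset serialization, and the command-level entry
# points (simulate | train | evaluate | verify) that the CLI script wraps.

generator_version <- "1"

default_run_config <- function() {
  list(
    seed = 1L,
    dataset = list(n_train = 200L, n_test = 50L, k = 1L, size = 64L,
                   noise_sd = 0.05, bias = TRUE, bias_amp = 0.15,
                   n_distractors = 0L,
                   train_classes = c(1L, 2L, 3L), test_classes = 4L,
                   mode = "setting2"),
    model = list(channels = c(8L, 8L), kernel = 3L),
    hyper = list(alpha = 0.01, beta = 0.001, inner_steps = 1L,
                 tasks_per_meta_batch = 1L, second_order = TRUE,
                 lr_decay = 0.98, decay_every = 1000L, clip = Inf),
    loss = list(w_ce = 1, w_ahd = 0, metric = "chebyshev", threshold = 0.5,
                ahd_warmup = 0L),
    method = "bmkfo",
    eval = list(inner_steps = 5L, use_optimizer = TRUE),
    export_png = FALSE)
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(base)) {
      stop_bmkfo("unknown config key: ", path, nm,
                 class = "bmkfo_invalid_argument")
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]])) {
        stop_bmkfo("config key ", path, nm, " must be a mapping",
                   class = "bmkfo_invalid_argument")
      }
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(path, nm, "."))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read a run configuration
#'
#' YAML key-value file (or a named list) merged over the package defaults;
#' unknown keys are rejected rather than silently ignored.
#'
#' @param path A YAML file path, a named list, or `NULL` for pure defaults.
#' @param overrides Optional named list applied after the file.
#' @return The full configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- if (is.character(path)) yaml::read_yaml(path) else path
    cfg <- merge_config(cfg, user)
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  cfg
}

config_plan <- function(cfg) {
  split_plan(cfg$dataset$train_classes, cfg$dataset$test_classes,
             cfg$dataset$mode)
}

config_dataset <- function(cfg) {
  ds <- cfg$dataset
  make_dataset(config_plan(cfg), n_train = ds$n_train, n_test = ds$n_test,
               k = ds$k, seed = cfg$seed, size = ds$size,
               noise_sd = ds$noise_sd, bias = ds$bias,
               bias_amp = ds$bias_amp, n_distractors = ds$n_distractors)
}

config_spec <- function(cfg) {
  seg_model_spec(channels = cfg$model$channels, kernel = cfg$model$kernel)
}

config_hyper <- function(cfg) {
  do.call(hyper_config, cfg$hyper)
}

#' Write / read an episodic dataset directory
#'
#' One serialized episode per file plus a JSON manifest (class ids, per-
#' episode seeds, split setting, generator version). Identical configuration
#' and seed reproduce identical files.
#'
#' @param dataset A `meta_dataset`.
#' @param dir Output directory (created if missing).
#' @return `save_dataset` returns the manifest invisibly; `load_dataset`
#'   returns the `meta_dataset`.
#' @export
save_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "meta_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_split <- function(eps, split) {
    for (i in seq_along(eps)) {
      saveRDS(eps[[i]], file.path(dir, sprintf("%s_%04d.rds", split, i)),
              compress = FALSE)
    }
    lapply(eps, function(e) {
      list(class_id = e$class_id, seed = e$seed,
           distractor_classes = as.list(e$distractor_classes))
    })
  }
  manifest <- list(
    generator_version = generator_version,
    seed = dataset$seed,
    mode = dataset$plan$mode,
    train_classes = as.list(dataset$plan$train_classes),
    test_classes = as.list(dataset$plan$test_classes),
    n_train = length(dataset$train),
    n_test = length(dataset$test),
    train = write_split(dataset$train, "train"),
    test = write_split(dataset$test, "test"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    stop_bmkfo("no manifest.json in ", dir, class = "bmkfo_invalid_argument")
  }
  manifest <- jsonlite::read_json(mpath)
  read_split <- function(split, n) {
    lapply(seq_len(n), function(i) {
      readRDS(file.path(dir, sprintf("%s_%04d.rds", split, i)))
    })
  }
  plan <- split_plan(unlist(manifest$train_classes),
                     unlist(manifest$test_classes), manifest$mode)
  structure(list(train = read_split("train", manifest$n_train),
                 test = read_split("test", manifest$n_test),
                 plan = plan, seed = manifest$seed),
            class = "meta_dataset")
}

#' Export an episode as PNG images
#'
#' 8-bit grayscale PNGs: masks as 0/255, images rescaled from `[0, 1]`.
#'
#' @param episode An episode.
#' @param prefix File-path prefix; `_support1.png`, `_support1_mask.png`,
#'   `_query.png`, `_query_mask.png` are appended.
#' @return The written paths, invisibly.
#' @export
export_episode_png <- function(episode, prefix) {
  paths <- character(0)
  wr <- function(m, suffix) {
    p <- paste0(prefix, suffix, ".png")
    png::writePNG(m, p)
    paths <<- c(paths, p)
  }
  for (i in seq_along(episode$support)) {
    wr(episode$support[[i]]$image, paste0("_support", i))
    wr(episode$support[[i]]$mask, paste0("_support", i, "_mask"))
  }
  wr(episode$query$image, "_query")
  wr(episode$query$mask, "_query_mask")
  invisible(paths)
}

#' Read a grayscale image or binary mask from PNG
#'
#' Color images are averaged to grayscale; masks are thresholded at 0.5
#' (8-bit mask PNGs written by [export_episode_png()] use 0/255).
#'
#' @param path PNG file path.
#' @return `read_image_png`: a numeric matrix in `[0, 1]`;
#'   `read_mask_png`: a binary 0/1 matrix.
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- apply(x[, , 1:min(3, dim(x)[3]), drop = FALSE],
                                       c(1, 2), mean)
  matrix(as.numeric(x), nrow(x), ncol(x))
}

#' @rdname read_image_png
#' @export
read_mask_png <- function(path) {
  (read_image_png(path) >= 0.5) * 1
}

write_config_echo <- function(cfg, dir) {
  yaml::write_yaml(cfg, file.path(dir, "config_echo.yaml"))
}

#' Generate and write a dataset (simulate command)
#'
#' Generates the configured episodic dataset, runs the class-split hygiene
#' audit (any setting-2 violation is an error), and writes the episode files,
#' manifest, audit CSV and a config echo to `out_dir`.
#'
#' @param config A configuration from [read_run_config()] (or a path / list
#'   accepted by it).
#' @param out_dir Output directory.
#' @return The dataset, invisibly.
#' @export
run_simulate <- function(config = NULL, out_dir) {
  cfg <- if (is.list(config) && !is.null(config$dataset)) config else read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dataset <- config_dataset(cfg)
  audit <- audit_split(dataset)
  if (cfg$dataset$mode == "setting2" && any(audit$violates)) {
    stop_bmkfo("setting-2 hygiene audit failed: test-class content in ",
               sum(audit$violates), " training episodes",
               class = "bmkfo_audit_error")
  }
  save_dataset(dataset, out_dir)
  readr::write_csv(audit, file.path(out_dir, "audit.csv"))
  write_config_echo(cfg, out_dir)
  if (isTRUE(cfg$export_png) && length(dataset$train) > 0) {
    export_episode_png(dataset$train[[1]], file.path(out_dir, "episode1"))
  }
  message(sprintf("wrote %d train + %d test episodes to %s (audit: %d violations)",
                  length(dataset$train), length(dataset$test), out_dir,
                  sum(audit$violates)))
  invisible(dataset)
}

#' Train a model (train command)
#'
#' Loads (or generates) the dataset, meta-trains with the configured method,
#' and writes `checkpoint.rds`, `training_log.csv` and a config echo.
#'
#' @inheritParams run_simulate
#' @param dataset_dir Optional dataset directory from [run_simulate()]; if
#'   `NULL` the dataset is generated from the config.
#' @param resume Optional path of a checkpoint to resume from.
#' @return The final `meta_state`, invisibly.
#' @export
run_train <- function(config = NULL, out_dir, dataset_dir = NULL,
                      resume = NULL) {
  cfg <- if (is.list(config) && !is.null(config$dataset)) config else read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dataset <- if (is.null(dataset_dir)) {
    config_dataset(cfg)
  } else {
    load_dataset(dataset_dir)
  }
  spec <- config_spec(cfg)
  state <- if (is.null(resume)) NULL else checkpoint_load(resume)
  episodes <- dataset$train
  if (!is.null(state)) {
    done <- state$iter * cfg$hyper$tasks_per_meta_batch
    episodes <- if (done >= length(episodes)) list() else episodes[-seq_len(done)]
  }
  state <- train_meta(spec, episodes, hyper = config_hyper(cfg),
                      method = cfg$method,
                      weights = c(cfg$loss$w_ce, cfg$loss$w_ahd),
                      metric = cfg$loss$metric, threshold = cfg$loss$threshold,
                      seed = cfg$seed, ahd_warmup = cfg$loss$ahd_warmup,
                      state = state)
  checkpoint_save(state, file.path(out_dir, "checkpoint.rds"))
  readr::write_csv(tibble::as_tibble(attr(state, "log")),
                   file.path(out_dir, "training_log.csv"))
  write_config_echo(cfg, out_dir)
  invisible(state)
}

#' Evaluate a checkpoint (evaluate command)
#'
#' Writes a per-episode metrics CSV, an aggregate JSON, and prints the
#' percentage table (Dice | Precision | Recall | Mean).
#'
#' @inheritParams run_train
#' @param checkpoint A checkpoint path or a `meta_state`.
#' @return The `metric_report`, invisibly.
#' @export
run_evaluate <- function(config = NULL, checkpoint, out_dir,
                         dataset_dir = NULL) {
  cfg <- if (is.list(config) && !is.null(config$dataset)) config else read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- if (inherits(checkpoint, "meta_state")) {
    checkpoint
  } else {
    checkpoint_load(checkpoint)
  }
  dataset <- if (is.null(dataset_dir)) {
    config_dataset(cfg)
  } else {
    load_dataset(dataset_dir)
  }
  report <- evaluate_meta(state, dataset$test,
                          inner_steps = cfg$eval$inner_steps,
                          use_optimizer = cfg$eval$use_optimizer,
                          metric = cfg$loss$metric,
                          threshold = cfg$loss$threshold)
  readr::write_csv(tibble::as_tibble(report),
                   file.path(out_dir, "metrics_per_episode.csv"))
  agg <- glance(report)
  jsonlite::write_json(as.list(agg), file.path(out_dir, "metrics_aggregate.json"),
                       auto_unbox = TRUE, digits = NA)
  write_config_echo(cfg, out_dir)
  print(format_metric_table(report))
  invisible(report)
}

# ---- verify command: self-contained oracle checks ------------------------

brute_directed_hd <- function(X, Y, metric) {
  worst <- 0
  for (i in seq_len(nrow(X))) {
    best <- Inf
    for (j in seq_len(nrow(Y))) {
      d <- point_distance(X[i, ], Y[j, ], metric)
      if (d < best) best <- d
    }
    if (best > worst) worst <- best
  }
  worst
}

brute_ahd <- function(X, Y, metric) {
  f <- function(A, B) {
    mean(vapply(seq_len(nrow(A)), function(i) {
      min(vapply(seq_len(nrow(B)), function(j) {
        point_distance(A[i, ], B[j, ], metric)
      }, numeric(1)))
    }, numeric(1)))
  }
  (f(X, Y) + f(Y, X)) / 2
}

random_mask_pair <- function(size) {
  repeat {
    a <- matrix(rbinom(size * size, 1, runif(1, 0.05, 0.5)), size, size)
    b <- matrix(rbinom(size * size, 1, runif(1, 0.05, 0.5)), size, size)
    if (sum(a) > 0 && sum(b) > 0) return(list(a = a, b = b))
  }
}

#' Run the built-in verification suite (verify command)
#'
#' Recomputes the package's key identities against brute-force oracles:
#' set-distance agreement (directed Hausdorff, symmetric Hausdorff, average
#' Hausdorff, distance transforms under all three metrics), the Kronecker
#' vec-identity, gradient-descent recovery of the bidirectional step at
#' identity factors, and the Dice/precision/recall identities. Any failure
#' raises an error.
#'
#' @param n_pairs Random mask pairs per distance check.
#' @param seed RNG seed.
#' @param tol Named tolerances (defaults: exact distances 0, Kronecker 1e-10,
#'   recovery 1e-10).
#' @return A tibble (check, cases, max_error, pass), invisibly; also printed.
#' @export
run_verify <- function(n_pairs = 25, seed = 1,
                       tol = c(distance = 0, kron = 1e-10, recovery = 1e-10,
                               metrics = 1e-12)) {
  rows <- list()
  add <- function(check, cases, max_error, tolerance) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      check = check, cases = cases, max_error = max_error,
      tolerance = tolerance, pass = max_error <= tolerance)
  }
  with_seed(seed, {
    err_hd <- 0; err_ahd <- 0; err_dt <- 0
    n_dist <- 0L
    for (metric in c("manhattan", "euclidean", "chebyshev")) {
      for (i in seq_len(n_pairs)) {
        mp <- random_mask_pair(12)
        X <- mask_to_pointset(mp$a); Y <- mask_to_pointset(mp$b)
        err_hd <- max(err_hd,
                      abs(directed_hd(X, Y, metric) - brute_directed_hd(X, Y, metric)),
                      abs(hd_loss(X, Y, metric) -
                            max(brute_directed_hd(X, Y, metric),
                                brute_directed_hd(Y, X, metric))))
        err_ahd <- max(err_ahd, abs(ahd(X, Y, metric) - brute_ahd(X, Y, metric)))
        D <- distance_transform(mp$a, metric)
        pts <- as.matrix(expand.grid(r = 0:(nrow(mp$a) - 1), c = 0:(ncol(mp$a) - 1)))
        Db <- matrix(vapply(seq_len(nrow(pts)), function(k) {
          min(pairwise_distances(pts[k, , drop = FALSE], X, metric))
        }, numeric(1)), nrow(mp$a), ncol(mp$a))
        err_dt <- max(err_dt, max(abs(D - Db)))
        n_dist <- n_dist + 1L
      }
    }
    add("directed/symmetric Hausdorff vs brute force", n_dist, err_hd,
        tol["distance"])
    add("average Hausdorff vs brute force", n_dist, err_ahd, tol["distance"])
    add("distance transform vs brute force", n_dist, err_dt, tol["distance"])

    err_k <- 0
    n_k <- 0L
    for (m in 2:4) {
      for (n in 2:4) {
        G <- matrix(rnorm(m * n), m, n)
        Fp <- factor_pair(matrix(rnorm(m * m), m, m), matrix(rnorm(n * n), n, n))
        lhs <- as.vector(apply_factored(G, Fp))
        rhs <- as.vector(kron(t(Fp$right), Fp$left) %*% as.vector(G))
        err_k <- max(err_k, max(abs(lhs - rhs)))
        n_k <- n_k + 1L
      }
    }
    add("Kronecker vec-identity", n_k, err_k, tol["kron"])

    # gradient-descent recovery: the meta-test update at identity factors
    # must equal a plain gradient-descent step theta' - alpha * grad(theta')
    theta <- list(W = matrix(rnorm(6), 2, 3))
    c0 <- matrix(rnorm(6), 2, 3)
    support <- function(th) list(value = 0.5 * sum((th$W - c0)^2),
                                 grad = list(W = th$W - c0))
    theta_p <- list(W = theta$W - 0.01 * (theta$W - c0))
    meta_test <- inner_adapt(theta_p, support, 0.05, 1,
                             xi = identity_optim_params(theta))
    ref <- theta_p$W - 0.05 * (theta_p$W - c0)
    add("gradient-descent recovery at identity factors", 1L,
        max(abs(meta_test$W - ref)), tol["recovery"])

    err_m <- 0
    for (i in 1:20) {
      pr <- matrix(rbinom(64, 1, 0.5), 8, 8)
      gt <- matrix(rbinom(64, 1, 0.5), 8, 8)
      cc <- confusion(pr, gt)
      p <- precision(cc); r <- recall(cc); d <- dice(cc)
      if (p + r > 0) err_m <- max(err_m, abs(d - 2 * p * r / (p + r)))
      tp <- sum(pr & gt)
      err_m <- max(err_m,
                   abs(cc["tp"] - tp),
                   abs(cc["fp"] - sum(pr & !gt)),
                   abs(cc["fn"] - sum(!pr & gt)))
    }
    add("metric identities (Dice harmonic mean, counts)", 20L, err_m,
        tol["metrics"])
  })
  out <- dplyr::bind_rows(rows)
  print(as.data.frame(out))
  if (!all(out$pass)) {
    stop_bmkfo("verification failed: ",
               paste(out$check[!out$pass], collapse = "; "),
               class = "bmkfo_verify_error")
  }
  invisible(out)
}
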