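# Seeded generator of organ-like 1-way k-shot segmentation episodes:
# radial-harmonic blob masks, MRI-style intensity rendering (noise, smooth
# multiplicative bias field, confusable distractor blobs), superpixel-style
# pseudo-labels, and class-split dataset assembly.

#' Define a shape class
#'
#' A shape class fixes the geometry and intensity statistics that support and
#' query examples of one episode share: an ellipse with random radial-harmonic
#' boundary perturbation, plus foreground/background intensity means. It is a
#' toy stand-in for an organ class (compact blob, distinct intensity, smooth
#' wobbling boundary).
#'
#' @param id Integer class id.
#' @param r_major Range (fraction of grid side) of the semi-major axis.
#' @param aspect Range of the minor/major axis ratio.
#' @param n_harmonics Number of radial harmonics perturbing the boundary.
#' @param perturb_amp Maximum total relative amplitude of the perturbation.
#' @param fg_mean,bg_mean Foreground / background intensity means in `[0, 1]`.
#' @param frac_bounds Accepted foreground-fraction interval for generated
#'   masks (rejection sampled).
#' @return A `shape_class` object.
#' @export
shape_class <- function(id,
                        r_major = c(0.15, 0.28),
                        aspect = c(0.55, 0.9),
                        n_harmonics = 3,
                        perturb_amp = 0.15,
                        fg_mean = 0.75,
                        bg_mean = 0.30,
                        frac_bounds = c(0.02, 0.4)) {
  if (perturb_amp < 0 || perturb_amp >= 0.5) {
    stop_bmkfo("perturb_amp must lie in [0, 0.5) to keep shapes star-convex",
               class = "bmkfo_invalid_argument")
  }
  structure(list(id = as.integer(id), r_major = r_major, aspect = aspect,
                 n_harmonics = as.integer(n_harmonics),
                 perturb_amp = perturb_amp, fg_mean = fg_mean,
                 bg_mean = bg_mean, frac_bounds = frac_bounds),
            class = "shape_class")
}

#' Default shape-class pool
#'
#' Four classes with distinct geometry (small rounded, large, elongated,
#' mid-sized irregular), all sharing the same foreground intensity so that
#' distractors of one class are confusable with another — the regime in which
#' organs of similar brightness are hard to tell apart.
#'
#' @param fg_mean,bg_mean Intensity means shared by all classes.
#' @return A named list of [shape_class()] objects (ids 1 to 4).
#' @export
default_shape_classes <- function(fg_mean = 0.75, bg_mean = 0.30) {
  list(
    shape_class(1, r_major = c(0.12, 0.18), aspect = c(0.7, 0.95),
                n_harmonics = 2, perturb_amp = 0.08,
                fg_mean = fg_mean, bg_mean = bg_mean),
    shape_class(2, r_major = c(0.24, 0.32), aspect = c(0.6, 0.85),
                n_harmonics = 3, perturb_amp = 0.12,
                fg_mean = fg_mean, bg_mean = bg_mean),
    shape_class(3, r_major = c(0.18, 0.26), aspect = c(0.35, 0.55),
                n_harmonics = 2, perturb_amp = 0.10,
                fg_mean = fg_mean, bg_mean = bg_mean),
    shape_class(4, r_major = c(0.15, 0.22), aspect = c(0.6, 0.9),
                n_harmonics = 4, perturb_amp = 0.18,
                fg_mean = fg_mean, bg_mean = bg_mean))
}

# Rasterize one perturbed ellipse; returns a logical matrix.
raster_blob <- function(size, center, a, b, psi, amps, phases) {
  rr <- matrix(seq_len(size) - 1, size, size)
  cc <- t(rr)
  dy <- rr - center[1]
  dx <- cc - center[2]
  u <- dx * cos(psi) + dy * sin(psi)
  v <- -dx * sin(psi) + dy * cos(psi)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  phi <- atan2(v / b, u / a)
  scale <- 1
  for (j in seq_along(amps)) {
    scale <- scale + amps[j] * cos(j * phi + phases[j])
  }
  rho <= scale
}

# 4-connected component count via vectorized flood fill from one fg pixel.
is_single_component <- function(mask) {
  fg <- mask == 1
  n_fg <- sum(fg)
  if (n_fg == 0) return(FALSE)
  reached <- matrix(FALSE, nrow(mask), ncol(mask))
  start <- which(fg)[1]
  reached[start] <- TRUE
  repeat {
    grown <- reached |
      rbind(FALSE, reached[-nrow(reached), ]) |
      rbind(reached[-1, ], FALSE) |
      cbind(FALSE, reached[, -ncol(reached)]) |
      cbind(reached[, -1], FALSE)
    grown <- grown & fg
    if (sum(grown) == sum(reached)) break
    reached <- grown
  }
  sum(reached) == n_fg
}

#' Generate one organ-like binary mask
#'
#' Rejection-samples a radial-harmonic-perturbed ellipse until it is a single
#' 4-connected component with foreground fraction inside the class bounds.
#' With zero perturbation amplitude the mask is an exact rasterized ellipse
#' (area close to `pi*a*b`).
#'
#' @param cls A [shape_class()].
#' @param size Grid side length in pixels.
#' @param seed Optional integer; if given, generation is run under this seed
#'   (identical seed, identical mask).
#' @param max_tries Rejection-sampling budget.
#' @return A binary mask matrix of dimension `size x size`.
#' @export
make_shape_mask <- function(cls, size = 64, seed = NULL, max_tries = 100) {
  stopifnot(inherits(cls, "shape_class"))
  gen <- function() {
    for (try in seq_len(max_tries)) {
      center <- runif(2, 0.32 * size, 0.68 * size)
      a <- runif(1, cls$r_major[1], cls$r_major[2]) * size
      b <- a * runif(1, cls$aspect[1], cls$aspect[2])
      psi <- runif(1, 0, pi)
      amps <- if (cls$n_harmonics > 0 && cls$perturb_amp > 0) {
        w <- runif(cls$n_harmonics)
        w / sum(w) * cls$perturb_amp
      } else {
        rep(0, max(cls$n_harmonics, 1))
      }
      phases <- runif(max(cls$n_harmonics, 1), 0, 2 * pi)
      mask <- raster_blob(size, center, a, b, psi, amps, phases) * 1
      frac <- mean(mask)
      if (frac >= cls$frac_bounds[1] && frac <= cls$frac_bounds[2] &&
          is_single_component(mask)) {
        return(mask)
      }
    }
    stop_bmkfo("failed to generate a valid mask for class ", cls$id,
               " after ", max_tries, " tries",
               class = "bmkfo_generation_error")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Smooth multiplicative bias field: low-order random polynomial in
# normalized coordinates, rescaled so the field stays within 1 +/- amp.
bias_field <- function(size, amp) {
  x <- matrix(seq(-1, 1, length.out = size), size, size)
  y <- t(x)
  coef <- runif(5, -1, 1)
  f <- coef[1] * x + coef[2] * y + coef[3] * x * y + coef[4] * x^2 + coef[5] * y^2
  f <- f - mean(f)
  m <- max(abs(f))
  if (m > 0) f <- f / m
  1 + amp * f
}

#' Render an MRI-like grayscale image for a mask
#'
#' Pixel intensity is the class foreground/background mean, plus optional
#' confusable distractor blobs painted at foreground intensity in the
#' background, plus additive Gaussian noise, optionally multiplied by a
#' smooth low-order polynomial bias field, clipped to `[0, 1]`.
#'
#' @param mask Target binary mask.
#' @param cls The [shape_class()] of the target.
#' @param noise_sd Gaussian noise standard deviation (must be >= 0).
#' @param bias Logical: apply a multiplicative bias field.
#' @param bias_amp Relative amplitude of the bias field.
#' @param distractor_classes List of [shape_class()] objects to draw
#'   distractor blobs from (possibly empty). Distractors share the foreground
#'   intensity but are background in the label: the confusable regime.
#' @param n_distractors Number of distractor blobs.
#' @param seed Optional integer seed.
#' @return The image matrix in `[0, 1]`, with attribute
#'   `"distractor_classes"`: integer ids of the distractors actually drawn.
#' @export
render_image <- function(mask, cls, noise_sd = 0.05, bias = TRUE,
                         bias_amp = 0.15, distractor_classes = list(),
                         n_distractors = 0, seed = NULL) {
  assert_binary_mask(mask)
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop_bmkfo("noise_sd must be nonnegative", class = "bmkfo_invalid_argument")
  }
  gen <- function() {
    size <- nrow(mask)
    img <- cls$bg_mean + (cls$fg_mean - cls$bg_mean) * mask
    used <- integer(0)
    if (n_distractors > 0 && length(distractor_classes) > 0) {
      for (d in seq_len(n_distractors)) {
        dcls <- distractor_classes[[sample.int(length(distractor_classes), 1)]]
        dmask <- tryCatch(make_shape_mask(dcls, size = size, max_tries = 50),
                          bmkfo_generation_error = function(e) NULL)
        if (is.null(dmask)) next
        paint <- dmask == 1 & mask == 0
        img[paint] <- dcls$fg_mean
        used <- c(used, dcls$id)
      }
    }
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
    if (bias) img <- img * bias_field(size, bias_amp)
    img <- pmin(pmax(img, 0), 1)
    img <- matrix(img, size, size)
    attr(img, "distractor_classes") <- used
    img
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate one 1-way k-shot episode
#'
#' Support and query examples share the same shape class (independent draws
#' of geometry and rendering).
#'
#' @param cls A [shape_class()].
#' @param k Number of support examples (default 1: one-way one-shot).
#' @param size Grid side.
#' @param seed Integer seed; the episode is a pure function of
#'   `(cls, k, size, seed, rendering options)`.
#' @inheritParams render_image
#' @return An `episode`: list with `support` (list of `list(image, mask)`),
#'   `query` (`list(image, mask)`), `class_id`, `distractor_classes`, `seed`.
#' @export
make_episode <- function(cls, k = 1, size = 64, seed = 1, noise_sd = 0.05,
                         bias = TRUE, bias_amp = 0.15,
                         distractor_classes = list(), n_distractors = 0) {
  stopifnot(inherits(cls, "shape_class"), k >= 1)
  with_seed(seed, {
    draw_pair <- function() {
      mask <- make_shape_mask(cls, size = size)
      img <- render_image(mask, cls, noise_sd = noise_sd, bias = bias,
                          bias_amp = bias_amp,
                          distractor_classes = distractor_classes,
                          n_distractors = n_distractors)
      list(image = img, mask = mask)
    }
    support <- lapply(seq_len(k), function(i) draw_pair())
    query <- draw_pair()
    dcl <- unique(c(
      unlist(lapply(support, function(s) attr(s$image, "distractor_classes"))),
      attr(query$image, "distractor_classes")))
    structure(list(support = support, query = query, class_id = cls$id,
                   distractor_classes = as.integer(dcl), seed = seed),
              class = "episode")
  })
}

#' Superpixel-style pseudo-label partition
#'
#' Partitions an image into `n_regions` connected regions by seeded
#' multi-source shortest-path label propagation: the cost of a path step into
#' pixel `p` for the region seeded at `s` is `1 + lambda * |I(p) - I(s)|`, so
#' regions follow intensity structure. On a constant image the partition
#' reduces to Manhattan-metric Voronoi cells of the seeds (cost ties broken
#' toward the lower seed index). One region is sampled uniformly and returned
#' as a pseudo foreground mask for self-supervised episodes.
#'
#' @param image Numeric image matrix.
#' @param n_regions Number of regions (>= 2, at most the pixel count).
#' @param seed Optional integer seed (controls seed-pixel placement and the
#'   sampled region).
#' @param lambda Intensity weight of the step cost.
#' @return A list: `labels` (integer matrix, every pixel assigned exactly one
#'   region), `pseudo_mask` (binary mask of the sampled region), `seeds`
#'   (pointset of the region seeds, 0-based).
#' @export
superpixel_pseudolabels <- function(image, n_regions, seed = NULL, lambda = 20) {
  if (!is.matrix(image) || !all(is.finite(image))) {
    stop_bmkfo("image must be a finite numeric matrix",
               class = "bmkfo_invalid_argument")
  }
  n_regions <- as.integer(n_regions)
  if (n_regions < 2L || n_regions > length(image)) {
    stop_bmkfo("n_regions must be in [2, number of pixels]",
               class = "bmkfo_invalid_argument")
  }
  gen <- function() {
    h <- nrow(image); w <- ncol(image)
    seed_lin <- sort(sample.int(h * w, n_regions))
    seed_int <- image[seed_lin]
    D <- matrix(Inf, h, w)
    Lab <- matrix(NA_integer_, h, w)
    D[seed_lin] <- 0
    Lab[seed_lin] <- seq_len(n_regions)
    shift <- function(M, dr, dc, fill) {
      out <- matrix(fill, h, w)
      rs <- seq_len(h) - dr; cs <- seq_len(w) - dc
      ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
      out[ok_r, ok_c] <- M[rs[ok_r], cs[ok_c]]
      out
    }
    eps <- 1e-9
    for (iter in seq_len(4L * (h + w))) {
      changed <- FALSE
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        Dn <- shift(D, d[1], d[2], Inf)
        Ln <- shift(Lab, d[1], d[2], NA_integer_)
        has <- !is.na(Ln)
        step <- matrix(Inf, h, w)
        step[has] <- 1 + lambda * abs(image[has] - seed_int[Ln[has]])
        cand <- Dn + step
        better <- has & (cand < D - eps |
                           (abs(cand - D) <= eps & !is.na(Lab) & Ln < Lab))
        if (any(better)) {
          D[better] <- cand[better]
          Lab[better] <- Ln[better]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    pick <- sample.int(n_regions, 1)
    seeds_rc <- cbind((seed_lin - 1L) %% h, (seed_lin - 1L) %/% h)
    list(labels = Lab,
         pseudo_mask = (Lab == pick) * 1,
         seeds = as_pointset(seeds_rc))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Define a class-split plan
#'
#' Setting 1: the held-out test class may still appear in the *background*
#' of training imagery (as a distractor blob). Setting 2: test-class pixels
#' are removed from training data entirely — class id sets must be disjoint
#' and the training distractor pool excludes test classes.
#'
#' @param train_classes,test_classes Integer vectors of class ids.
#' @param mode `"setting1"` or `"setting2"`.
#' @return A `split_plan` object.
#' @export
split_plan <- function(train_classes, test_classes,
                       mode = c("setting1", "setting2")) {
  mode <- match.arg(mode)
  train_classes <- as.integer(train_classes)
  test_classes <- as.integer(test_classes)
  if (length(train_classes) == 0L || length(test_classes) == 0L) {
    stop_bmkfo("class lists must be non-empty", class = "bmkfo_invalid_argument")
  }
  if (mode == "setting2" && length(intersect(train_classes, test_classes)) > 0) {
    stop_bmkfo("setting2 requires disjoint train/test class ids",
               class = "bmkfo_invalid_argument")
  }
  structure(list(train_classes = train_classes, test_classes = test_classes,
                 mode = mode),
            class = "split_plan")
}

#' Generate a seeded episodic dataset
#'
#' Training episodes cycle over the plan's training classes; test episodes
#' over its test classes. Under setting 2, training-image backgrounds never
#' contain a test-class shape (the distractor pool is restricted); under
#' setting 1 they may. Fully deterministic in `(plan, sizes, seed, options)`.
#'
#' @param plan A [split_plan()].
#' @param n_train,n_test Episode counts (either may be 0).
#' @param k Shots per episode.
#' @param seed Root seed; per-episode seeds are derived substreams.
#' @param classes Class pool (list of [shape_class()]) indexed by id;
#'   defaults to [default_shape_classes()].
#' @param size Grid side.
#' @inheritParams render_image
#' @param distractor_fg_mean Optional intensity at which distractor blobs are
#'   painted. `NULL` (default) keeps each distractor class's own foreground
#'   mean — fully confusable with the target; a value between the background
#'   and foreground means gives distractors that are distinguishable in
#'   principle but still attract false-positive mass.
#' @return A `meta_dataset`: list with `train`, `test` episode lists and the
#'   generating `plan` and `seed`.
#' @export
make_dataset <- function(plan, n_train, n_test, k = 1, seed = 1,
                         classes = default_shape_classes(), size = 64,
                         noise_sd = 0.05, bias = TRUE, bias_amp = 0.15,
                         n_distractors = 0, distractor_fg_mean = NULL) {
  stopifnot(inherits(plan, "split_plan"))
  ids <- vapply(classes, function(c) c$id, integer(1))
  get_cls <- function(id) classes[[match(id, ids)]]
  pool_ids <- function(split) {
    if (split == "train" && plan$mode == "setting2") {
      setdiff(ids, plan$test_classes)
    } else {
      ids
    }
  }
  gen_split <- function(split, n, class_ids) {
    if (n == 0) return(list())
    pool <- lapply(pool_ids(split), get_cls)
    if (!is.null(distractor_fg_mean)) {
      pool <- lapply(pool, function(cl) {
        cl$fg_mean <- distractor_fg_mean
        cl
      })
    }
    lapply(seq_len(n), function(i) {
      cid <- class_ids[((i - 1L) %% length(class_ids)) + 1L]
      make_episode(get_cls(cid), k = k, size = size,
                   seed = derive_seed(seed, paste0(split, "-", i)),
                   noise_sd = noise_sd, bias = bias, bias_amp = bias_amp,
                   distractor_classes = pool,
                   n_distractors = n_distractors)
    })
  }
  structure(list(train = gen_split("train", n_train, plan$train_classes),
                 test = gen_split("test", n_test, plan$test_classes),
                 plan = plan, seed = seed),
            class = "meta_dataset")
}

#' Audit class-split hygiene of a dataset
#'
#' Scans every training episode (target class and all distractor classes
#' actually drawn) for test-class instances. Under setting 2 the count must
#' be zero.
#'
#' @param dataset A `meta_dataset` from [make_dataset()].
#' @return A tibble with one row per training episode: `episode`, `class_id`,
#'   `distractors`, `violates` (logical).
#' @export
audit_split <- function(dataset) {
  stopifnot(inherits(dataset, "meta_dataset"))
  test_ids <- dataset$plan$test_classes
  rows <- purrr::imap(dataset$train, function(ep, i) {
    seen <- c(ep$class_id, ep$distractor_classes)
    tibble::tibble(episode = i, class_id = ep$class_id,
                   distractors = paste(ep$distractor_classes, collapse = ","),
                   violates = any(seen %in% test_ids))
  })
  dplyr::bind_rows(rows)
}
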