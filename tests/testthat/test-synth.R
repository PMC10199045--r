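# Synthetic episode generator: geometry, rendering statistics, pseudo-label
# partitions, split hygiene, determinism, and solvability.

test_that("zero-perturbation masks are exact rasterized ellipses", {
  cls <- shape_class(1, r_major = c(0.3, 0.3), aspect = c(0.7, 0.7),
                     n_harmonics = 0, perturb_amp = 0)
  mask <- make_shape_mask(cls, size = 64, seed = 5)
  a <- 0.3 * 64; b <- a * 0.7
  expect_lt(abs(sum(mask) - pi * a * b) / (pi * a * b), 0.02)
  expect_equal(oracle_n_components(mask), 1L)
})

test_that("mask generation is deterministic and respects class invariants", {
  cls <- default_shape_classes()[[4]]
  m1 <- make_shape_mask(cls, seed = 11)
  m2 <- make_shape_mask(cls, seed = 11)
  expect_identical(m1, m2)
  expect_false(identical(m1, make_shape_mask(cls, seed = 12)))
  set.seed(100)
  for (i in 1:40) {
    m <- make_shape_mask(cls, size = 48)
    expect_equal(oracle_n_components(m), 1L)
    frac <- mean(m)
    expect_gte(frac, cls$frac_bounds[1])
    expect_lte(frac, cls$frac_bounds[2])
  }
})

test_that("rendering produces the configured intensity structure", {
  cls <- shape_class(1, fg_mean = 0.8, bg_mean = 0.2)
  mask <- make_shape_mask(cls, seed = 3)
  img <- render_image(mask, cls, noise_sd = 0, bias = FALSE, seed = 3)
  expect_setequal(unique(as.vector(img)), c(0.2, 0.8))
  # invisible foreground when means coincide
  flat_cls <- shape_class(1, fg_mean = 0.5, bg_mean = 0.5)
  flat <- render_image(mask, flat_cls, noise_sd = 0, bias = FALSE, seed = 3)
  expect_equal(mean(flat[mask == 1]) - mean(flat[mask == 0]), 0)
  # empirical foreground mean within 3 standard errors over repeated renders
  set.seed(4)
  n_img <- 50
  fg_means <- vapply(seq_len(n_img), function(i) {
    im <- render_image(mask, cls, noise_sd = 0.05, bias = FALSE)
    mean(im[mask == 1])
  }, numeric(1))
  se <- 0.05 / sqrt(sum(mask) * n_img)
  expect_lt(abs(mean(fg_means) - 0.8), 3 * se + 1e-3) # clipping bias allowance
  expect_error(render_image(mask, cls, noise_sd = -1),
               class = "bmkfo_invalid_argument")
})

test_that("superpixel pseudo-labels partition the grid and reduce to Voronoi on flat images", {
  set.seed(5)
  img <- matrix(runif(24 * 24), 24, 24)
  sp <- superpixel_pseudolabels(img, n_regions = 6, seed = 9)
  expect_true(all(!is.na(sp$labels)))
  expect_setequal(unique(as.vector(sp$labels)), 1:6)
  expect_true(all(sp$pseudo_mask %in% c(0, 1)))
  expect_gt(sum(sp$pseudo_mask), 0)
  sp2 <- superpixel_pseudolabels(img, n_regions = 6, seed = 9)
  expect_identical(sp$labels, sp2$labels)
  # constant image: labels must equal Manhattan Voronoi cells of the seeds
  flat <- matrix(1, 16, 16)
  spf <- superpixel_pseudolabels(flat, n_regions = 5, seed = 21)
  ref <- oracle_voronoi_manhattan(16, 16, unclass(spf$seeds))
  expect_identical(unname(spf$labels), unname(ref))
  expect_error(superpixel_pseudolabels(flat, n_regions = 300),
               class = "bmkfo_invalid_argument")
  expect_error(superpixel_pseudolabels(flat, n_regions = 1),
               class = "bmkfo_invalid_argument")
})

test_that("datasets are deterministic and setting-2 hygiene is auditable", {
  plan <- split_plan(c(1, 2), 3, "setting2")
  d1 <- make_dataset(plan, n_train = 6, n_test = 4, seed = 7, size = 32,
                     n_distractors = 2)
  d2 <- make_dataset(plan, n_train = 6, n_test = 4, seed = 7, size = 32,
                     n_distractors = 2)
  expect_identical(d1, d2)
  audit <- audit_split(d1)
  expect_equal(nrow(audit), 6)
  expect_false(any(audit$violates))
  # distractors were actually drawn, and only from the permitted pool
  dcl <- unlist(lapply(d1$train, `[[`, "distractor_classes"))
  expect_gt(length(dcl), 0)
  expect_true(all(dcl %in% c(1, 2, 4)))
  # setting 1 permits test-class distractors in training backgrounds
  plan1 <- split_plan(c(1, 2), 3, "setting1")
  d3 <- make_dataset(plan1, n_train = 12, n_test = 0, seed = 7, size = 32,
                     n_distractors = 2)
  expect_equal(length(d3$test), 0)
  d0 <- make_dataset(plan, n_train = 0, n_test = 3, seed = 7, size = 32)
  expect_equal(length(d0$train), 0)
  expect_equal(length(d0$test), 3)
  expect_error(split_plan(c(1, 2), c(2, 3), "setting2"),
               class = "bmkfo_invalid_argument")
  expect_error(split_plan(integer(0), 1), class = "bmkfo_invalid_argument")
})

test_that("episodes share a class between support and query and are solvable by oracle thresholding", {
  cls <- default_shape_classes()[[2]]
  ep <- make_episode(cls, k = 2, size = 48, seed = 13)
  expect_length(ep$support, 2)
  expect_equal(ep$class_id, cls$id)
  expect_true(all(ep$query$image >= 0 & ep$query$image <= 1))
  expect_identical(ep, make_episode(cls, k = 2, size = 48, seed = 13))
  # high-contrast regime: thresholding at the midpoint of the noise-free
  # fg/bg means recovers the mask almost perfectly
  mid <- (cls$fg_mean + cls$bg_mean) / 2
  dices <- vapply(1:20, function(i) {
    e <- make_episode(cls, size = 48, seed = 500 + i, noise_sd = 0.03,
                      bias = FALSE)
    pred <- (e$query$image >= mid) * 1
    dice(confusion(pred, e$query$mask))
  }, numeric(1))
  expect_gt(mean(dices), 0.95)
})
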