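# Confusion-count segmentation metrics and tidy evaluation reports.

#' Pixelwise confusion counts
#'
#' @param pred,gt Binary masks of equal shape.
#' @return A `confusion_counts` object: named integer vector
#'   `c(tp, fp, fn, tn)` summing to the pixel count.
#' @export
confusion <- function(pred, gt) {
  assert_binary_mask(pred)
  assert_binary_mask(gt)
  if (!all(dim(pred) == dim(gt))) {
    stop_bmkfo("pred and gt shapes differ", class = "bmkfo_shape_error")
  }
  tp <- sum(pred == 1 & gt == 1)
  fp <- sum(pred == 1 & gt == 0)
  fn <- sum(pred == 0 & gt == 1)
  tn <- sum(pred == 0 & gt == 0)
  structure(c(tp = tp, fp = fp, fn = fn, tn = tn), class = "confusion_counts")
}

as_counts <- function(c) {
  if (inherits(c, "confusion_counts")) return(unclass(c))
  c <- unlist(c)
  if (!all(c("tp", "fp", "fn") %in% names(c))) {
    stop_bmkfo("counts need named tp, fp, fn entries",
               class = "bmkfo_invalid_argument")
  }
  c
}

# 0/0 convention: both masks empty -> 1 (perfect agreement on absence);
# exactly one empty -> 0. Standard segmentation-benchmark convention.
rate_or_convention <- function(num, den, tp, fp, fn) {
  if (tp + fp + fn == 0) return(1)
  if (den == 0) return(0)
  unname(num / den)
}

#' Precision (positive predictive value)
#' @param c Confusion counts from [confusion()].
#' @return `tp / (tp + fp)` in `[0, 1]`; both-empty masks give 1,
#'   an empty prediction against non-empty truth gives 0.
#' @export
precision <- function(c) {
  c <- as_counts(c)
  rate_or_convention(c["tp"], c["tp"] + c["fp"], c["tp"], c["fp"], c["fn"])
}

#' Recall (sensitivity)
#' @inheritParams precision
#' @return `tp / (tp + fn)` in `[0, 1]` with the same degenerate conventions
#'   as [precision()].
#' @export
recall <- function(c) {
  c <- as_counts(c)
  rate_or_convention(c["tp"], c["tp"] + c["fn"], c["tp"], c["fp"], c["fn"])
}

#' Dice coefficient (F1)
#'
#' `2 tp / (2 tp + fp + fn)`: the harmonic mean of precision and recall
#' whenever their sum is positive.
#' @inheritParams precision
#' @return A value in `[0, 1]`.
#' @export
dice <- function(c) {
  c <- as_counts(c)
  rate_or_convention(2 * c["tp"], 2 * c["tp"] + c["fp"] + c["fn"],
                     c["tp"], c["fp"], c["fn"])
}

#' Evaluate a set of predicted masks against ground truth
#'
#' @param pred A list of binary masks (or a single mask).
#' @param gt A list of binary masks matched to `pred`.
#' @param episode_id,class_id Optional vectors recycled across pairs.
#' @param metric Distance metric for the exact average-Hausdorff column.
#' @return A `metric_report` tibble with one row per pair: `episode_id`,
#'   `class_id`, `dice`, `precision`, `recall`, `ahd`. For an empty
#'   prediction against non-empty truth the AHD column holds the grid
#'   diameter; if both are empty it is 0.
#' @export
evaluate_predictions <- function(pred, gt, episode_id = NULL, class_id = NA_integer_,
                                 metric = "chebyshev") {
  if (is.matrix(pred)) pred <- list(pred)
  if (is.matrix(gt)) gt <- list(gt)
  stopifnot(length(pred) == length(gt))
  n <- length(pred)
  if (is.null(episode_id)) episode_id <- seq_len(n)
  episode_id <- rep_len(episode_id, n)
  class_id <- rep_len(class_id, n)
  rows <- purrr::map(seq_len(n), function(i) {
    cc <- confusion(pred[[i]], gt[[i]])
    P <- mask_to_pointset(pred[[i]])
    G <- mask_to_pointset(gt[[i]])
    a <- if (nrow(P) > 0 && nrow(G) > 0) {
      ahd(P, G, metric)
    } else if (nrow(P) == 0 && nrow(G) == 0) {
      0
    } else {
      grid_diameter(dim(gt[[i]]), metric)
    }
    tibble::tibble(episode_id = episode_id[i], class_id = class_id[i],
                   dice = dice(cc), precision = precision(cc),
                   recall = recall(cc), ahd = a)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("metric_report", class(out))
  out
}

#' @export
print.metric_report <- function(x, ...) {
  NextMethod()
  agg <- glance(x)
  cat(sprintf(
    "Mean over %d episodes: Dice %.2f | Precision %.2f | Recall %.2f | AHD %.2f px\n",
    nrow(x), 100 * agg$dice, 100 * agg$precision, 100 * agg$recall, agg$ahd))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a metric report (one row per episode)
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.metric_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Aggregate a metric report: arithmetic means over episodes
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return A one-row tibble with mean `dice`, `precision`, `recall`, `ahd`
#'   and `n_episodes`.
#' @export
glance.metric_report <- function(x, ...) {
  dplyr::summarise(tibble::as_tibble(x),
                   dice = mean(.data$dice),
                   precision = mean(.data$precision),
                   recall = mean(.data$recall),
                   ahd = mean(.data$ahd),
                   n_episodes = dplyr::n())
}

#' Plot per-episode metric distributions
#' @param object A `metric_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metric_report <- function(object, ...) {
  long <- tidyr_pivot(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~scale, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-episode segmentation quality") +
    ggplot2::theme_minimal()
}

# Minimal long-format reshape (rates on one panel, AHD pixels on another).
tidyr_pivot <- function(x) {
  x <- tibble::as_tibble(x)
  rates <- dplyr::bind_rows(
    tibble::tibble(metric = "dice", value = x$dice),
    tibble::tibble(metric = "precision", value = x$precision),
    tibble::tibble(metric = "recall", value = x$recall))
  rates$scale <- "rate"
  a <- tibble::tibble(metric = "ahd", value = x$ahd, scale = "pixels")
  dplyr::bind_rows(rates, a)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Format a metric report as a percentage table
#'
#' Aggregate row with Dice/precision/recall as percentages (two decimals)
#' and a `Mean` column over the three rates, matching the conventional
#' benchmark-table style.
#' @param x A `metric_report`.
#' @return A one-row tibble of formatted strings.
#' @export
format_metric_table <- function(x) {
  g <- glance(x)
  m <- mean(c(g$dice, g$precision, g$recall))
  tibble::tibble(
    `Dice score` = sprintf("%.2f", 100 * g$dice),
    Precision = sprintf("%.2f", 100 * g$precision),
    Recall = sprintf("%.2f", 100 * g$recall),
    Mean = sprintf("%.2f", 100 * m),
    `AHD (px)` = sprintf("%.2f", g$ahd))
}
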