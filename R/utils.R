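# Internal validation and RNG helpers.

stop_bmkfo <- function(..., class) {
  stop(rlang::error_cnd(class = c(class, "bmkfo_error"), message = paste0(...)))
}

assert_finite_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_bmkfo(name, " must be a numeric matrix", class = "bmkfo_invalid_argument")
  }
  if (length(x) == 0L) {
    stop_bmkfo(name, " must be non-empty", class = "bmkfo_invalid_argument")
  }
  if (!all(is.finite(x))) {
    stop_bmkfo(name, " contains non-finite values", class = "bmkfo_invalid_argument")
  }
  invisible(x)
}

assert_binary_mask <- function(mask, name = deparse(substitute(mask))) {
  if (!is.matrix(mask) || length(mask) < 1L) {
    stop_bmkfo(name, " must be a non-empty matrix", class = "bmkfo_invalid_argument")
  }
  if (!all(mask %in% c(0, 1))) {
    stop_bmkfo(name, " must contain only 0/1 values", class = "bmkfo_invalid_argument")
  }
  invisible(mask)
}

assert_prob_map <- function(p, name = deparse(substitute(p))) {
  if (!is.matrix(p) || length(p) < 1L || !all(is.finite(p)) ||
      any(p < 0) || any(p > 1)) {
    stop_bmkfo(name, " must be a matrix with entries in [0, 1]",
               class = "bmkfo_invalid_argument")
  }
  invisible(p)
}

match_metric <- function(metric) {
  valid <- c("manhattan", "euclidean", "chebyshev")
  if (length(metric) != 1L || !metric %in% valid) {
    stop_bmkfo("unknown metric '", paste(metric, collapse = ","),
               "'; valid metrics: ", paste(valid, collapse = ", "),
               class = "bmkfo_invalid_argument")
  }
  metric
}

# Deterministic substream seeds: one root seed fans out to named streams so
# dataset generation, initialization and training draws never interleave.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h * 16807) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Flatten / unflatten a named list of numeric matrices (used by the
# finite-difference Hessian-vector products and parameter hashing).
flatten_params <- function(theta) {
  unlist(lapply(theta, as.vector), use.names = FALSE)
}

unflatten_params <- function(vec, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    out[[nm]] <- matrix(vec[(pos + 1L):(pos + n)],
                        nrow = nrow(template[[nm]]),
                        ncol = ncol(template[[nm]]))
    pos <- pos + n
  }
  out
}

params_axpy <- function(a, x, y) {
  # a * x + y elementwise over matched named lists of matrices
  out <- y
  for (nm in names(y)) out[[nm]] <- a * x[[nm]] + y[[nm]]
  out
}

params_scale <- function(a, x) {
  lapply(x, function(m) a * m)
}

params_norm <- function(x) {
  sqrt(sum(vapply(x, function(m) sum(m^2), numeric(1))))
}
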