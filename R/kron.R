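# Kronecker-product algebra for factored gradient preconditioning.

#' Kronecker product of two matrices
#'
#' Blockwise product: the output block at position (i, j) equals
#' `A[i, j] * B`. Used as a reference construction and test oracle; the
#' training path never materializes Kronecker matrices (see
#' [apply_factored()]).
#'
#' @param A,B Numeric matrices, all entries finite, non-empty.
#' @return A numeric matrix of dimension `(nrow(A)*nrow(B)) x (ncol(A)*ncol(B))`.
#' @examples
#' kron(diag(2), diag(2)) # identity of order 4
#' @export
kron <- function(A, B) {
  assert_finite_matrix(A, "A")
  assert_finite_matrix(B, "B")
  A %x% B
}

#' Kronecker factor pair of a gradient preconditioner
#'
#' A pair of square matrices `(L, R)` that precondition an `m x n` gradient
#' matrix `G` as `L %*% G %*% R`, equivalent to multiplying `vec(G)`
#' (column-major) by the Kronecker matrix `t(R) %x% L`. The identity pair
#' recovers plain gradient descent, which is the property that motivates the
#' Kronecker parameterization of the meta-optimizer.
#'
#' @param left An `m x m` numeric matrix.
#' @param right An `n x n` numeric matrix.
#' @param shape_tag Integer vector `c(m, n)`: the shape of the gradient
#'   matrix this pair preconditions.
#' @return An object of class `factor_pair`.
#' @seealso [identity_factors()], [apply_factored()]
#' @export
factor_pair <- function(left, right, shape_tag = c(nrow(left), nrow(right))) {
  assert_finite_matrix(left, "left")
  assert_finite_matrix(right, "right")
  if (nrow(left) != ncol(left) || nrow(right) != ncol(right)) {
    stop_bmkfo("factor matrices must be square", class = "bmkfo_invalid_argument")
  }
  shape_tag <- as.integer(shape_tag)
  if (length(shape_tag) != 2L || shape_tag[1] != nrow(left) ||
      shape_tag[2] != nrow(right)) {
    stop_bmkfo("shape_tag (", paste(shape_tag, collapse = "x"),
               ") does not match factor dimensions ",
               nrow(left), "x", nrow(right),
               class = "bmkfo_shape_error")
  }
  structure(list(left = left, right = right, shape_tag = shape_tag),
            class = "factor_pair")
}

#' Identity Kronecker factors
#'
#' @param m,n Positive integers: gradient matrix dimensions.
#' @return A `factor_pair` with `left = diag(m)`, `right = diag(n)`; applying
#'   it leaves every gradient unchanged.
#' @export
identity_factors <- function(m, n) {
  if (!is.numeric(m) || !is.numeric(n) || m < 1 || n < 1) {
    stop_bmkfo("dimensions must be positive integers",
               class = "bmkfo_invalid_argument")
  }
  factor_pair(diag(as.integer(m)), diag(as.integer(n)))
}

#' Apply a Kronecker-factored preconditioner to a gradient matrix
#'
#' Computes `L %*% G %*% R`, i.e. the action of the Kronecker matrix
#' `t(R) %x% L` on the column-major vectorization of `G`, without forming
#' the `mn x mn` matrix. Linear in `G`.
#'
#' @param G An `m x n` numeric gradient matrix.
#' @param F A [factor_pair()] whose `shape_tag` equals `dim(G)`.
#' @param name Optional parameter-tensor name used in shape-error messages.
#' @return An `m x n` numeric matrix.
#' @export
apply_factored <- function(G, F, name = "gradient") {
  if (!inherits(F, "factor_pair")) {
    stop_bmkfo("F must be a factor_pair", class = "bmkfo_invalid_argument")
  }
  if (!is.matrix(G)) G <- as.matrix(G)
  if (nrow(G) != F$shape_tag[1] || ncol(G) != F$shape_tag[2]) {
    stop_bmkfo("shape mismatch for parameter tensor '", name, "': gradient is ",
               nrow(G), "x", ncol(G), " but factors expect ",
               F$shape_tag[1], "x", F$shape_tag[2],
               class = "bmkfo_shape_error")
  }
  F$left %*% G %*% F$right
}

# Transpose action of the factored map: <W G, V> = <G, t(L) V t(R)>.
# Needed when backpropagating through a preconditioned update.
apply_factored_t <- function(V, F) {
  t(F$left) %*% V %*% t(F$right)
}

#' @export
print.factor_pair <- function(x, ...) {
  cat(sprintf("<factor_pair> L: %dx%d, R: %dx%d (preconditions %dx%d gradients)\n",
              nrow(x$left), ncol(x$left), nrow(x$right), ncol(x$right),
              x$shape_tag[1], x$shape_tag[2]))
  invisible(x)
}
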