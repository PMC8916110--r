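#' Upper-triangle edge index table
#'
#' Enumerates the undirected edges of an `n`-node graph as upper-triangle
#' index pairs (i < j), in the column-major order used throughout the
#' package to map between matrices and flat edge vectors.
#'
#' @param n_rois Number of nodes (ROIs).
#' @return A tibble with columns `edge`, `node_i`, `node_j` (1-based,
#'   `node_i < node_j`) and `n_rois * (n_rois - 1) / 2` rows.
#' @export
edge_index_table <- function(n_rois) {
  stopifnot(is.numeric(n_rois), length(n_rois) == 1, n_rois >= 2)
  n <- as.integer(n_rois)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  tibble::tibble(
    edge = seq_len(nrow(idx)),
    node_i = as.integer(idx[, 1]),
    node_j = as.integer(idx[, 2])
  )
}

# Flatten a stack (list of n x n matrices, or n x n x S array) to an
# S x E matrix of upper-triangle edge values, in edge_index_table() order.
stack_to_edge_matrix <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3) {
    stack <- lapply(seq_len(dim(stack)[3]), function(s) stack[, , s])
  }
  if (!is.list(stack) || length(stack) == 0) {
    stop("`stack` must be a non-empty list of matrices or a 3-d array", call. = FALSE)
  }
  n <- nrow(stack[[1]])
  ut <- upper.tri(stack[[1]])
  for (s in seq_along(stack)) {
    m <- stack[[s]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n) {
      stop(sprintf("matrix %d in the stack is not %d x %d", s, n, n), call. = FALSE)
    }
  }
  out <- vapply(stack, function(m) m[ut], numeric(sum(ut)))
  structure(t(out), n_rois = n)
}

# Rebuild a symmetric zero-diagonal matrix from a flat edge vector.
edge_vector_to_matrix <- function(values, n_rois) {
  m <- matrix(0, n_rois, n_rois)
  m[upper.tri(m)] <- values
  m + t(m)
}

# Map (i, j) pairs (i < j) to flat edge positions in the upper-triangle
# column-major order. `pairs` is a 2-column matrix or data frame.
edge_positions <- function(pairs, n_rois) {
  pairs <- as.matrix(pairs[, 1:2, drop = FALSE])
  i <- pmin(pairs[, 1], pairs[, 2])
  j <- pmax(pairs[, 1], pairs[, 2])
  if (any(i == j)) stop("self-loops are not valid edges", call. = FALSE)
  if (any(j > n_rois)) stop("edge index exceeds number of ROIs", call. = FALSE)
  # column-major upper triangle: edges preceding column j, plus row i
  as.integer((j - 1) * (j - 2) / 2 + i)
}

check_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("%s must be square", what), call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop(sprintf("%s must be symmetric", what), call. = FALSE)
  }
  invisible(m)
}
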