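#' Patch similarity graph and Laplacian
#'
#' Builds a mutual-k-nearest-neighbour graph over patch columns with
#' Gaussian edge weights W_ij = exp(-||x_i - x_j||^2 / (2 sigma^2)) and the
#' combinatorial Laplacian L = Diag(W 1) - W. W is symmetric with a zero
#' diagonal; L has zero row sums and is positive semidefinite.
#'
#' @param patchset a `patch_set` or n x M matrix.
#' @param k_neighbors neighbours per node (< number of patches).
#' @param kernel_sigma Gaussian bandwidth; `NULL` (default) uses the median
#'   pairwise distance.
#' @return object of class `similarity_graph`: list with sparse `W`, sparse
#'   `laplacian`, `k_neighbors`, `kernel_sigma`.
#' @export
build_similarity_graph <- function(patchset, k_neighbors = 8L,
                                   kernel_sigma = NULL) {
  X <- as_patch_matrix(patchset)
  Mp <- ncol(X)
  k <- as.integer(k_neighbors)
  if (k >= Mp) stop("`k_neighbors` must be < number of patches", call. = FALSE)
  if (k < 1L) stop("`k_neighbors` must be >= 1", call. = FALSE)
  if (!is.null(kernel_sigma) && kernel_sigma <= 0)
    stop("`kernel_sigma` must be > 0", call. = FALSE)

  nrm2 <- colSums(X^2)
  d2 <- outer(nrm2, nrm2, `+`) - 2 * crossprod(X)
  d2[d2 < 0] <- 0
  diag(d2) <- Inf
  if (is.null(kernel_sigma)) {
    off <- sqrt(d2[upper.tri(d2)])
    kernel_sigma <- max(stats::median(off), 1e-12)
  }
  # k nearest neighbours of each node (ties by index for determinism)
  nn <- apply(d2, 2L, function(col) order(col, seq_along(col))[seq_len(k)])
  A <- Matrix::sparseMatrix(i = as.vector(nn),
                            j = rep(seq_len(Mp), each = k),
                            x = 1, dims = c(Mp, Mp))
  mutual <- A * Matrix::t(A)                     # 1 iff i in knn(j) and j in knn(i)
  d2[!is.finite(d2)] <- 0
  W <- mutual * exp(-d2 / (2 * kernel_sigma^2))
  W <- (W + Matrix::t(W)) / 2
  deg <- Matrix::rowSums(W)
  L <- Matrix::Diagonal(x = deg) - W
  structure(list(W = W, laplacian = L, k_neighbors = k,
                 kernel_sigma = kernel_sigma),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph %d nodes, %d edges, sigma = %.4g>\n",
              nrow(x$W), Matrix::nnzero(x$W) / 2, x$kernel_sigma))
  invisible(x)
}

as_laplacian <- function(x) {
  if (inherits(x, "similarity_graph")) return(x$laplacian)
  if (is.matrix(x) || inherits(x, "Matrix")) return(x)
  stop("expected a similarity_graph or matrix", call. = FALSE)
}

#' Graph-Laplacian smoothness energy of a code matrix
#'
#' Tr(Gamma L Gamma^T), identically equal to the weighted pairwise form
#' (1/2) sum_ij W_ij ||alpha_i - alpha_j||^2: the penalty that pulls the
#' sparse codes of similar patches together.
#'
#' @param codes a `code_matrix` or J x M matrix.
#' @param graph a `similarity_graph` (or Laplacian matrix).
#' @return nonnegative scalar.
#' @export
laplacian_energy <- function(codes, graph) {
  G <- as_code_matrix(codes)
  L <- as_laplacian(graph)
  if (ncol(G) != nrow(L)) stop("codes/graph shape mismatch", call. = FALSE)
  GL <- G %*% L
  sum(GL * G)
}

# Embed a Laplacian over a node subset into the full column set: rows and
# columns outside `nodes` are zero, so only those codes feel the penalty.
embed_laplacian <- function(L_sub, nodes, n_total) {
  tr <- Matrix::summary(methods::as(L_sub, "TsparseMatrix"))
  Matrix::sparseMatrix(i = nodes[tr$i], j = nodes[tr$j], x = tr$x,
                       dims = c(n_total, n_total))
}
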