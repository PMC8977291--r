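#' Initialize a patch dictionary
#'
#' Overcomplete 2D separable DCT atoms (default) or seeded random unit-norm
#' atoms. Every column has unit Euclidean norm; the first DCT atom is the
#' constant (DC) atom.
#'
#' @param patch_dim patch dimension n = p^2.
#' @param n_atoms number of atoms J (>= patch_dim for an overcomplete
#'   dictionary; fewer triggers a warning).
#' @param method "dct" or "random".
#' @param seed seed for `method = "random"`.
#' @return object of class `sparse_dictionary`: list with `atoms`
#'   (n x J matrix), `patch_size`, `method`.
#' @export
init_dictionary <- function(patch_dim, n_atoms, method = c("dct", "random"),
                            seed = 1L) {
  method <- match.arg(method)
  n <- as.integer(patch_dim); J <- as.integer(n_atoms)
  if (n <= 0L || J <= 0L) stop("dimensions must be positive", call. = FALSE)
  if (J < n) warning("n_atoms < patch_dim: dictionary is undercomplete")
  p <- as.integer(round(sqrt(n)))
  if (method == "dct" && p * p == n) {
    L <- as.integer(ceiling(sqrt(J)))
    D1 <- matrix(0, p, L)
    for (k in seq_len(L)) {
      v <- cos((0:(p - 1) + 0.5) * (k - 1) * pi / L)
      if (k > 1L) v <- v - mean(v)
      D1[, k] <- v
    }
    D <- kronecker(D1, D1)[, seq_len(J), drop = FALSE]
  } else if (method == "dct") {
    L <- J
    D <- matrix(0, n, J)
    for (k in seq_len(J)) {
      v <- cos((0:(n - 1) + 0.5) * (k - 1) * pi / L)
      if (k > 1L) v <- v - mean(v)
      D[, k] <- v
    }
  } else {
    D <- with_seed(seed, matrix(rnorm(n * J), n, J))
  }
  D <- normalize_columns(D)
  structure(list(atoms = D, patch_size = p, method = method),
            class = "sparse_dictionary")
}

normalize_columns <- function(D) {
  nrm <- sqrt(colSums(D^2))
  nrm[nrm < 1e-12] <- 1
  sweep(D, 2L, nrm, "/")
}

#' @export
print.sparse_dictionary <- function(x, ...) {
  cat(sprintf("<sparse_dictionary %d x %d (%s)>\n",
              nrow(x$atoms), ncol(x$atoms), x$method))
  invisible(x)
}

as_atoms <- function(x) {
  if (inherits(x, "sparse_dictionary")) return(x$atoms)
  if (is.matrix(x)) return(x)
  stop("expected a sparse_dictionary or matrix", call. = FALSE)
}

as_patch_matrix <- function(x) {
  if (inherits(x, "patch_set")) return(x$X)
  if (is.matrix(x)) return(x)
  stop("expected a patch_set or matrix", call. = FALSE)
}

as_code_matrix <- function(x) {
  if (inherits(x, "code_matrix")) return(x$codes)
  if (is.matrix(x) || inherits(x, "Matrix")) return(x)
  stop("expected a code_matrix or matrix", call. = FALSE)
}

new_code_matrix <- function(codes, coder, extra = list()) {
  structure(c(list(codes = codes, coder = coder), extra),
            class = "code_matrix")
}

#' @export
print.code_matrix <- function(x, ...) {
  nz <- if (inherits(x$codes, "sparseMatrix"))
    Matrix::nnzero(x$codes) else sum(x$codes != 0)
  cat(sprintf("<code_matrix %d x %d (%s), %.2f nonzeros/column>\n",
              nrow(x$codes), ncol(x$codes), x$coder, nz / ncol(x$codes)))
  invisible(x)
}

#' Sparse coding by orthogonal matching pursuit
#'
#' Greedy per-column coder: repeatedly selects the atom with maximal
#' absolute correlation with the residual and re-fits the selected support
#' by least squares, until `sparsity_T` atoms are used or the residual norm
#' falls below `tol`.
#'
#' @param patchset a `patch_set` or n x M matrix of signals.
#' @param dictionary a `sparse_dictionary` or n x J matrix.
#' @param sparsity_T maximum support size per column (>= 1).
#' @param tol residual 2-norm stopping tolerance (default 1e-8).
#' @return a `code_matrix` whose `codes` are a sparse J x M matrix.
#' @export
sparse_code_omp <- function(patchset, dictionary, sparsity_T = 6L,
                            tol = 1e-8) {
  X <- as_patch_matrix(patchset)
  D <- as_atoms(dictionary)
  if (!all(is.finite(X))) stop("non-finite patch values", call. = FALSE)
  if (sparsity_T < 1L && tol <= 0) stop("need sparsity_T >= 1 or tol > 0",
                                        call. = FALSE)
  J <- ncol(D); Mp <- ncol(X)
  Tmax <- min(as.integer(sparsity_T), nrow(D), J)
  # Gram-space OMP: all dictionary-signal correlations are precomputed and
  # residual correlations maintained via the Gram matrix, so the per-patch
  # work is independent of the patch dimension.
  DtD <- crossprod(D)
  C <- crossprod(D, X)
  x2 <- colSums(X^2)
  ilist <- vector("list", Mp); xlist <- vector("list", Mp)
  for (m in seq_len(Mp)) {
    if (x2[m] <= tol^2) next
    c0 <- C[, m]
    supp <- integer(0); coef <- numeric(0)
    corr <- c0
    for (t in seq_len(Tmax)) {
      a <- abs(corr); a[supp] <- -1
      supp <- c(supp, which.max(a))
      Gss <- DtD[supp, supp, drop = FALSE]
      coef <- tryCatch(solve(Gss, c0[supp]),
                       error = function(e)
                         qr.coef(qr(Gss), c0[supp]))
      coef[is.na(coef)] <- 0
      res2 <- x2[m] - sum(c0[supp] * coef)
      if (res2 <= tol^2) break
      corr <- c0 - DtD[, supp, drop = FALSE] %*% coef
    }
    ilist[[m]] <- supp; xlist[[m]] <- as.numeric(coef)
  }
  lens <- vapply(ilist, length, 1L)
  codes <- Matrix::sparseMatrix(i = as.integer(unlist(ilist)),
                                j = rep(seq_len(Mp), lens),
                                x = as.numeric(unlist(xlist)),
                                dims = c(J, Mp))
  new_code_matrix(codes, "omp", list(sparsity_T = Tmax))
}

#' Gradient-step dictionary update
#'
#' One ascent-free update of the atoms toward the current patches: a
#' gradient step D <- D + xi * (X - D Gamma) Gamma^T followed by per-column
#' renormalization to unit norm. The step size is found by backtracking so
#' the Frobenius fit residual ||X - D Gamma||_F never increases; atoms that
#' collapse to zero norm are reseeded from the worst-fit patch.
#'
#' @param dictionary a `sparse_dictionary`.
#' @param patchset a `patch_set` or matrix X.
#' @param codes a `code_matrix` or J x M matrix Gamma.
#' @param xi initial step size; `NULL` (default) starts from
#'   1 / ||Gamma Gamma^T||_2.
#' @param max_backtracks halvings allowed before giving up (returns the
#'   renormalized input dictionary).
#' @return an updated `sparse_dictionary` with unit-norm columns.
#' @export
update_dictionary <- function(dictionary, patchset, codes, xi = NULL,
                              max_backtracks = 30L) {
  D0 <- normalize_columns(as_atoms(dictionary))
  X <- as_patch_matrix(patchset)
  G <- as_code_matrix(codes)
  R <- X - as.matrix(D0 %*% G)
  res0 <- norm(R, "F")
  GG <- as.matrix(Matrix::tcrossprod(G))
  if (is.null(xi)) {
    xi <- 1 / max(norm(GG, "2"), 1e-12)
  } else if (xi <= 0) stop("`xi` must be > 0", call. = FALSE)
  grad <- R %*% t(as.matrix(G))     # (X - D Gamma) Gamma^T
  D <- D0
  for (bt in seq_len(max_backtracks)) {
    Dc <- D0 + xi * grad
    nrm <- sqrt(colSums(Dc^2))
    dead <- which(nrm < 1e-12)
    if (length(dead)) {
      worst <- order(colSums((X - as.matrix(Dc %*% G))^2),
                     decreasing = TRUE)[seq_along(dead)]
      Dc[, dead] <- X[, worst, drop = FALSE] +
        1e-8 * seq_len(nrow(X))  # deterministic tie-break perturbation
    }
    Dc <- normalize_columns(Dc)
    if (norm(X - as.matrix(Dc %*% G), "F") <= res0 + 1e-10) {
      D <- Dc
      break
    }
    xi <- xi / 2
  }
  structure(list(atoms = D, patch_size = dictionary$patch_size,
                 method = dictionary$method),
            class = "sparse_dictionary")
}
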