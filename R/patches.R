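#' Extract image patches
#'
#' Vectorizes p x p patches at a raster of anchor positions into the
#' columns of an n x M_p matrix (n = p^2, column-major within a patch).
#' With `periodic = TRUE` patches wrap around the image boundary, so with
#' stride 1 there are exactly M*N patches and every pixel is covered by
#' exactly p^2 patches — the geometry under which the patch-consensus
#' normal operator is p^2 times the identity.
#'
#' @param image numeric matrix or phantom.
#' @param patch_size patch side p (<= min(M, N)).
#' @param stride anchor spacing (>= 1); a stride larger than `patch_size`
#'   leaves uncovered pixels and triggers a warning.
#' @param periodic wrap patches around the boundary (default TRUE).
#' @return object of class `patch_set`: list with `X` (n x M_p matrix),
#'   `index` (linear pixel index per patch entry), `patch_size`, `stride`,
#'   `periodic`, `source_shape`.
#' @export
extract_patches <- function(image, patch_size, stride = 1L, periodic = TRUE) {
  u <- as_image(image)
  M <- nrow(u); N <- ncol(u)
  p <- as.integer(patch_size); s <- as.integer(stride)
  if (p <= 0L || s <= 0L) stop("patch_size and stride must be positive",
                               call. = FALSE)
  if (p > min(M, N)) stop("patch_size exceeds image size", call. = FALSE)
  if (s > p) warning("stride > patch_size leaves uncovered pixels")

  r0 <- if (periodic) seq(1L, M, by = s) else seq(1L, M - p + 1L, by = s)
  c0 <- if (periodic) seq(1L, N, by = s) else seq(1L, N - p + 1L, by = s)
  # rows/cols covered by each anchor, wrapped if periodic
  off <- 0:(p - 1L)
  rows <- outer(off, r0 - 1L, `+`)            # p x length(r0)
  cols <- outer(off, c0 - 1L, `+`)
  if (periodic) { rows <- rows %% M; cols <- cols %% N }
  # linear index for patch (i,j): rows[,i] x cols[,j], column-major patches
  n_r <- length(r0); n_c <- length(c0)
  ridx <- rows[rep(seq_len(p), times = p), , drop = FALSE]    # p^2 x n_r
  cidx <- cols[rep(seq_len(p), each = p), , drop = FALSE]     # p^2 x n_c
  # combine anchors column-major: patch k = (i + (j-1)*n_r)
  idx <- matrix(0L, p * p, n_r * n_c)
  for (j in seq_len(n_c)) {
    cj <- cidx[, j]
    idx[, (j - 1L) * n_r + seq_len(n_r)] <- ridx + 1L +
      matrix(cj, p * p, n_r) * M
  }
  structure(list(X = matrix(u[idx], p * p, n_r * n_c), index = idx,
                 patch_size = p, stride = s, periodic = periodic,
                 source_shape = c(M, N)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set %d x %d (p = %d, stride = %d, %s)>\n",
              nrow(x$X), ncol(x$X), x$patch_size, x$stride,
              if (x$periodic) "periodic" else "interior"))
  invisible(x)
}

#' Reassemble an image from (possibly modified) patches
#'
#' Adjoint-and-normalize of [extract_patches()]: every pixel becomes the
#' average of all patch copies covering it. `reassemble_patches(ps, ps$X)`
#' is the identity.
#'
#' @param patchset a `patch_set`.
#' @param values matrix of the same shape as `patchset$X` (defaults to the
#'   extracted patches themselves).
#' @param average divide the accumulated sums by the per-pixel cover count
#'   (default TRUE); with `FALSE` the raw adjoint sum and the counts are
#'   returned.
#' @return the M x N image matrix (or, with `average = FALSE`, a list with
#'   `sum` and `count` matrices).
#' @export
reassemble_patches <- function(patchset, values = NULL, average = TRUE) {
  if (!inherits(patchset, "patch_set")) stop("expected a patch_set",
                                             call. = FALSE)
  if (is.null(values)) values <- patchset$X
  if (!all(dim(values) == dim(patchset$X)))
    stop("values shape does not match patch set", call. = FALSE)
  M <- patchset$source_shape[1]; N <- patchset$source_shape[2]
  ii <- as.vector(patchset$index)
  acc <- Matrix::sparseMatrix(i = ii, j = rep(1L, length(ii)),
                              x = as.vector(values), dims = c(M * N, 1L))
  cnt <- Matrix::sparseMatrix(i = ii, j = rep(1L, length(ii)),
                              x = 1, dims = c(M * N, 1L))
  s <- matrix(as.vector(acc), M, N)
  k <- matrix(as.vector(cnt), M, N)
  if (!average) return(list(sum = s, count = k))
  if (any(k == 0)) stop("patch geometry leaves uncovered pixels; cannot average",
                        call. = FALSE)
  s / k
}
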