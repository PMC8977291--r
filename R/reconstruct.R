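#' Reconstruction configuration
#'
#' Collects every tunable of the split-Bregman dictionary reconstruction.
#' Patch-model defaults: 8 x 8 patches, stride 2 while learning the
#' dictionary and stride 1 while coding, 4x overcomplete dictionary
#' (256 atoms), OMP target sparsity 6, l1 fit weight lambda = 1, graph
#' weight mu_graph = 0.01, split penalty beta = 1. The pipeline runs 15
#' outer Bregman iterations with 5 warm-started coding sweeps of 3 FISTA
#' steps each — chosen for reconstruction quality per unit time on a
#' single core (see the methods vignette); `sparse_code_bregman()` itself
#' defaults to 10 sweeps.
#'
#' @param mu k-space data-consistency weight (> 0).
#' @param beta augmented-Lagrangian penalty of the coder (> 0).
#' @param lambda residual-energy weight of the coder (> 0).
#' @param mu_graph graph-Laplacian weight (>= 0; 0 disables the graph).
#' @param xi dictionary-update step size; `NULL` = automatic backtracking.
#' @param n_outer outer Bregman iterations (>= 1).
#' @param n_inner coding sweeps per outer iteration.
#' @param n_ista ISTA steps per coding sweep.
#' @param patch_size patch side p.
#' @param stride_train patch stride during dictionary learning.
#' @param overcompleteness K; the dictionary has K * p^2 atoms.
#' @param sparsity_T OMP sparsity target (training and `coder = "omp"`).
#' @param coder "bregman" (graph-regularized l1, the primary coder) or
#'   "omp" (fast greedy alternative).
#' @param dict_iters,dict_iters_warm dictionary-learning alternations on
#'   the first / subsequent outer iterations (warm-started atoms).
#' @param max_train_patches dictionary learning uses at most this many
#'   seeded random training patches.
#' @param graph_max_nodes similarity graph is built on at most this many
#'   seeded random patch columns.
#' @param k_neighbors mutual-kNN neighbourhood size of the graph.
#' @param tol early-stop threshold on the relative image change.
#' @param seed integer seed for all internal randomness.
#' @param regularizer "dictionary" or "tv".
#' @param lambda_tv TV weight when `regularizer = "tv"`.
#' @param reference optional ground-truth image; when given, per-iteration
#'   PSNR is recorded in the history.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(mu = 100, beta = 1, lambda = 1, mu_graph = 0.01,
                         xi = NULL, n_outer = 15L, n_inner = 5L, n_ista = 3L,
                         patch_size = 8L, stride_train = 2L,
                         overcompleteness = 4L, sparsity_T = 6L,
                         coder = c("bregman", "omp"),
                         dict_iters = 3L, dict_iters_warm = 1L,
                         max_train_patches = 3000L,
                         graph_max_nodes = 2000L, k_neighbors = 8L,
                         tol = 1e-6, seed = 1L,
                         regularizer = c("dictionary", "tv"),
                         lambda_tv = 2, reference = NULL) {
  coder <- match.arg(coder)
  regularizer <- match.arg(regularizer)
  if (mu <= 0 || beta <= 0 || lambda <= 0) stop("weights must be > 0",
                                                call. = FALSE)
  if (mu_graph < 0) stop("`mu_graph` must be >= 0", call. = FALSE)
  if (n_outer < 1L) stop("`n_outer` must be >= 1", call. = FALSE)
  structure(list(mu = mu, beta = beta, lambda = lambda, mu_graph = mu_graph,
                 xi = xi, n_outer = as.integer(n_outer),
                 n_inner = as.integer(n_inner), n_ista = as.integer(n_ista),
                 patch_size = as.integer(patch_size),
                 stride_train = as.integer(stride_train),
                 overcompleteness = as.integer(overcompleteness),
                 sparsity_T = as.integer(sparsity_T), coder = coder,
                 dict_iters = as.integer(dict_iters),
                 dict_iters_warm = as.integer(dict_iters_warm),
                 max_train_patches = as.integer(max_train_patches),
                 graph_max_nodes = as.integer(graph_max_nodes),
                 k_neighbors = as.integer(k_neighbors),
                 tol = tol, seed = as.integer(seed),
                 regularizer = regularizer, lambda_tv = lambda_tv,
                 reference = reference),
            class = "recon_config")
}

#' Zero-filled baseline reconstruction
#'
#' Real part of the inverse FFT of the mask-restricted k-space: the naive
#' reference every compressed-sensing method must beat.
#'
#' @param kspace `kspace` object or complex matrix.
#' @param mask `sampling_mask` or logical matrix.
#' @return real M x N matrix.
#' @export
zero_fill_baseline <- function(kspace, mask) {
  v <- as_kspace_values(kspace)
  m <- as_mask_matrix(mask)
  if (!all(dim(v) == dim(m))) stop("kspace/mask shape mismatch", call. = FALSE)
  Re(ifft2c(v * m))
}

#' Closed-form image update of the dictionary reconstruction
#'
#' Exact minimizer of
#' (beta/2) sum_i ||D alpha_i - R_i u||^2 + (mu/2) ||F_p u - f_k||^2
#' under periodic stride-1 patch geometry (where sum_i R_i^T R_i = p^2 I):
#' in k-space, u_hat = (beta p^2 FFT(u_bar) + mu mask o f_k) /
#' (beta p^2 + mu mask), with u_bar the overlap-averaged patch consensus
#' image. The real part is returned.
#'
#' @param codes `code_matrix` (or matrix Gamma).
#' @param dictionary `sparse_dictionary`.
#' @param patchset the stride-1 periodic `patch_set` giving the geometry.
#' @param f_k current (Bregman-updated) k-space data, zero off-mask.
#' @param mask `sampling_mask` or logical matrix.
#' @param mu,beta data and patch weights (not both zero).
#' @return real M x N image matrix.
#' @export
update_image <- function(codes, dictionary, patchset, f_k, mask,
                         mu = 100, beta = 1) {
  if (mu == 0 && beta == 0) stop("mu = beta = 0 leaves u undetermined",
                                 call. = FALSE)
  if (!inherits(patchset, "patch_set") || patchset$stride != 1L ||
      !patchset$periodic)
    stop("update_image requires periodic stride-1 patch geometry",
         call. = FALSE)
  D <- as_atoms(dictionary)
  G <- as_code_matrix(codes)
  m <- as_mask_matrix(mask)
  fk <- as_kspace_values(f_k)
  p2 <- patchset$patch_size^2
  u_bar <- reassemble_patches(patchset, as.matrix(D %*% G))
  num <- beta * p2 * fft2c(u_bar) + mu * m * fk
  den <- beta * p2 + mu * m
  Re(ifft2c(num / den))
}

#' Bregman residual feedback
#'
#' The "add back the residual" step f_{k+1} = f_k + f - F_p u, applied on
#' the mask support only (off-mask entries stay zero).
#'
#' @param f_k current Bregman data (`kspace` or complex matrix).
#' @param f_measured measured data.
#' @param u_next new image estimate.
#' @param mask `sampling_mask` or logical matrix.
#' @return a `kspace` object.
#' @export
bregman_feedback <- function(f_k, f_measured, u_next, mask) {
  m <- as_mask_matrix(mask)
  fk <- as_kspace_values(f_k)
  f0 <- as_kspace_values(f_measured)
  if (!all(dim(fk) == dim(m)) || !all(dim(f0) == dim(m)))
    stop("shape mismatch", call. = FALSE)
  structure(list(values = (fk + f0 - fft2c(u_next)) * m), class = "kspace")
}

#' Split-Bregman dictionary-learning reconstruction
#'
#' Recovers an image from undersampled k-space by alternating, per outer
#' Bregman iteration: patch extraction from the current estimate,
#' dictionary (re-)learning on strided training patches (warm-started
#' atoms), graph-regularized sparse coding of all stride-1 patches, the
#' closed-form k-space image update, and the Bregman residual feedback on
#' the measured data. The estimate starts from the zero-filled inverse.
#'
#' @param kspace measured data (`kspace` object or complex matrix), zero
#'   off-mask.
#' @param mask `sampling_mask` or logical matrix.
#' @param config a [recon_config()].
#' @return list with `image` (final estimate clipped to \[0, 255\]) and
#'   `state`, a `bregman_state` carrying `u_k`, `f_k`, `k` and a per-
#'   iteration `history` data frame (objective, data residual, relative
#'   change, PSNR when a reference was supplied).
#' @export
reconstruct <- function(kspace, mask, config = recon_config()) {
  if (!inherits(config, "recon_config")) stop("`config` must be a recon_config",
                                              call. = FALSE)
  if (config$regularizer == "tv")
    return(reconstruct_tv(kspace, mask, lambda_tv = config$lambda_tv,
                          mu = config$mu, n_outer = config$n_outer,
                          reference = config$reference))
  m <- as_mask_matrix(mask)
  f0 <- as_kspace_values(kspace) * m
  p <- config$patch_size
  n_atoms <- config$overcompleteness * p^2

  u <- zero_fill_baseline(f0, m)
  f_k <- f0
  dict <- init_dictionary(p^2, n_atoms, method = "dct")
  hist <- vector("list", config$n_outer)
  k_done <- 0L
  codes_prev <- NULL    # warm start for the l1 coder across outer iterations

  for (k in seq_len(config$n_outer)) {
    # dictionary (re-)learning on strided training patches, warm-started
    train <- extract_patches(u, p, stride = config$stride_train)
    if (ncol(train$X) > config$max_train_patches) {
      keep <- with_seed(config$seed + 1000L + k,
                        sort(sample(ncol(train$X), config$max_train_patches)))
      train$X <- train$X[, keep, drop = FALSE]
    }
    n_alt <- if (k == 1L) config$dict_iters else config$dict_iters_warm
    for (a in seq_len(n_alt)) {
      g_tr <- sparse_code_omp(train, dict, sparsity_T = config$sparsity_T)
      dict <- update_dictionary(dict, train, g_tr, xi = config$xi)
    }

    # graph-regularized coding of all stride-1 patches
    ps <- extract_patches(u, p, stride = 1L)
    graph <- NULL
    if (config$mu_graph > 0) {
      Mp <- ncol(ps$X)
      nodes <- if (Mp > config$graph_max_nodes)
        with_seed(config$seed + k,
                  sort(sample(Mp, config$graph_max_nodes))) else seq_len(Mp)
      g_sub <- build_similarity_graph(ps$X[, nodes, drop = FALSE],
                                      k_neighbors = config$k_neighbors)
      graph <- embed_laplacian(g_sub$laplacian, nodes, Mp)
    }
    if (config$coder == "bregman") {
      sc <- sparse_code_bregman(ps, dict, graph = graph,
                                lambda = config$lambda,
                                mu_graph = config$mu_graph,
                                beta = config$beta,
                                n_inner = config$n_inner,
                                n_ista = config$n_ista,
                                init = codes_prev)
      codes <- sc$codes
      codes_prev <- sc$codes$codes
      obj <- sc$objective[length(sc$objective)]
    } else {
      codes <- sparse_code_omp(ps, dict, sparsity_T = config$sparsity_T)
      obj <- NA_real_
    }

    u_new <- update_image(codes, dict, ps, f_k, m,
                          mu = config$mu, beta = config$beta)
    if (!all(is.finite(u_new)))
      stop(sprintf("non-finite image at outer iteration %d (image update)", k),
           call. = FALSE)
    f_k <- bregman_feedback(f_k, f0, u_new, m)$values

    rel <- sqrt(sum((u_new - u)^2)) / max(sqrt(sum(u^2)), 1e-12)
    resid <- sqrt(sum(Mod(fft2c(u_new) * m - f0)^2))
    hist[[k]] <- data.frame(
      iter = k, objective = obj, data_residual = resid, rel_change = rel,
      psnr = if (is.null(config$reference)) NA_real_ else
        psnr(config$reference, clip01(u_new, 0, 255)))
    u <- u_new
    k_done <- k
    if (rel < config$tol) break
  }

  state <- structure(list(u_k = u, f_k = f_k, k = k_done,
                          history = do.call(rbind, hist[seq_len(k_done)])),
                     class = "bregman_state")
  list(image = clip01(u, 0, 255), state = state)
}

#' @export
print.bregman_state <- function(x, ...) {
  cat(sprintf("<bregman_state after %d outer iteration(s)>\n", x$k))
  print(x$history)
  invisible(x)
}

#' Split-Bregman total-variation reconstruction (baseline)
#'
#' Isotropic-TV compressed-sensing baseline: min_u lambda_tv TV(u) +
#' (mu/2)||F_p u - f^k||^2 solved by splitting the image gradient with
#' shrinkage, plus the same outer Bregman data feedback as the dictionary
#' method. `lambda_tv = 0` degenerates to the zero-filled solution.
#'
#' @param kspace measured data, zero off-mask.
#' @param mask `sampling_mask` or logical matrix.
#' @param lambda_tv TV weight (>= 0).
#' @param mu data-consistency weight (> 0).
#' @param n_outer outer Bregman iterations.
#' @param n_inner inner split-Bregman sweeps per outer iteration.
#' @param gamma split penalty on the gradient constraint.
#' @param reference optional ground truth for per-iteration PSNR.
#' @return real M x N image matrix (clipped to \[0, 255\]).
#' @export
reconstruct_tv <- function(kspace, mask, lambda_tv = 2, mu = 100,
                           n_outer = 8L, n_inner = 10L, gamma = NULL,
                           reference = NULL) {
  m <- as_mask_matrix(mask)
  f0 <- as_kspace_values(kspace) * m
  if (lambda_tv < 0) stop("`lambda_tv` must be >= 0", call. = FALSE)
  if (mu <= 0) stop("`mu` must be > 0", call. = FALSE)
  if (lambda_tv == 0) return(clip01(zero_fill_baseline(f0, m), 0, 255))
  if (is.null(gamma)) gamma <- lambda_tv
  M <- nrow(m); N <- ncol(m)
  # periodic forward differences diagonalized by the DFT
  ex <- exp(2i * pi * (0:(M - 1)) / M) - 1          # row-direction eigenvalues
  ey <- exp(2i * pi * (0:(N - 1)) / N) - 1
  lap_eig <- outer(Mod(ex)^2, rep(1, N)) + outer(rep(1, M), Mod(ey)^2)
  grad_r <- function(u) u[c(2:M, 1), , drop = FALSE] - u
  grad_c <- function(u) u[, c(2:N, 1), drop = FALSE] - u
  grad_adj <- function(dx, dy)                       # adjoint of (grad_r, grad_c)
    (dx[c(M, 1:(M - 1)), , drop = FALSE] - dx) +
    (dy[, c(N, 1:(N - 1)), drop = FALSE] - dy)

  u <- zero_fill_baseline(f0, m)
  f_k <- f0
  dx <- dy <- bx <- by <- matrix(0, M, N)
  for (k in seq_len(n_outer)) {
    for (it in seq_len(n_inner)) {
      rhs <- mu * f_k + gamma * fft2c(grad_adj(dx - bx, dy - by))
      u_hat <- rhs / (mu * m + gamma * lap_eig + 1e-12)
      u <- Re(ifft2c(u_hat))
      gx <- grad_r(u) + bx
      gy <- grad_c(u) + by
      mag <- sqrt(gx^2 + gy^2)
      shrink <- pmax(mag - lambda_tv / gamma, 0) / pmax(mag, 1e-12)
      dx <- gx * shrink
      dy <- gy * shrink
      bx <- gx - dx
      by <- gy - dy
    }
    f_k <- bregman_feedback(f_k, f0, u, m)$values
    if (!all(is.finite(u)))
      stop(sprintf("non-finite image at outer iteration %d (tv)", k),
           call. = FALSE)
  }
  clip01(u, 0, 255)
}
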