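test_that("patch extraction and reassembly are exact inverses", {
  const <- matrix(7, 16, 16)
  ps <- extract_patches(const, 4)
  expect_true(all(ps$X == 7))

  tiny <- extract_patches(matrix(1:16, 4, 4), 2, stride = 1, periodic = TRUE)
  expect_equal(ncol(tiny$X), 16L)          # M*N patches
  expect_equal(nrow(tiny$X), 4L)

  set.seed(4)
  u <- matrix(rnorm(64), 8, 8)
  ps <- extract_patches(u, 3)
  expect_equal(reassemble_patches(ps), u, tolerance = 1e-12)

  cnt <- reassemble_patches(ps, average = FALSE)$count
  expect_true(all(cnt == 9))               # p^2 covers per pixel

  expect_true(all(reassemble_patches(ps, matrix(0, 9, 64)) == 0))
  expect_error(reassemble_patches(ps, matrix(0, 3, 3)), "shape")
  expect_warning(extract_patches(u, 2, stride = 3), "stride")
  expect_error(extract_patches(u, 20), "exceeds")
})

test_that("dictionary initialization gives unit-norm deterministic atoms", {
  D <- init_dictionary(64, 256)
  expect_equal(dim(D$atoms), c(64L, 256L))
  expect_equal(colSums(D$atoms^2), rep(1, 256), tolerance = 1e-12)
  expect_identical(D$atoms, init_dictionary(64, 256)$atoms)
  # DC atom: constant with value 1/sqrt(n)
  expect_equal(D$atoms[, 1], rep(1 / 8, 64), tolerance = 1e-12)

  Dr <- init_dictionary(16, 32, method = "random", seed = 2)
  expect_equal(colSums(Dr$atoms^2), rep(1, 32), tolerance = 1e-12)
  expect_warning(init_dictionary(16, 8), "undercomplete")
})

test_that("OMP recovers exact atoms and zero signals", {
  D <- init_dictionary(16, 32, method = "random", seed = 1)
  x <- 3.5 * D$atoms[, 3]
  g <- sparse_code_omp(matrix(x, ncol = 1), D, sparsity_T = 4)
  expect_equal(as.vector(g$codes[3, 1]), 3.5, tolerance = 1e-10)
  expect_equal(sum(g$codes != 0), 1L)

  gz <- sparse_code_omp(matrix(0, 16, 2), D, 4)
  expect_true(all(gz$codes == 0))
  expect_error(sparse_code_omp(matrix(NaN, 16, 1), D, 2), "finite")
})

test_that("OMP matches the exhaustive best-support oracle on 5-atom dictionaries", {
  # oracle: least-squares fit over every C(5,2) support
  best_support_resid <- function(x, D, T) {
    supports <- utils::combn(ncol(D), T)
    min(apply(supports, 2, function(s) {
      cf <- qr.coef(qr(D[, s, drop = FALSE]), x)
      sqrt(sum((x - D[, s, drop = FALSE] %*% cf)^2))
    }))
  }
  # signals are noisy 2-sparse combinations of the atoms: the regime the
  # sparsity-T coder is specified for
  set.seed(7)
  n_equal <- 0L
  for (trial in 1:100) {
    D <- matrix(rnorm(8 * 5), 8, 5)
    D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
    s0 <- sample(5, 2)
    x <- as.vector(D[, s0] %*% runif(2, 0.5, 2)) + rnorm(8, sd = 0.05)
    g <- sparse_code_omp(matrix(x, ncol = 1), D, sparsity_T = 2, tol = 0)
    r_omp <- sqrt(sum((x - D %*% g$codes[, 1])^2))
    r_best <- best_support_resid(x, D, 2)
    expect_gte(r_omp, r_best - 1e-9)       # greedy can never beat exhaustive
    if (r_omp <= r_best + 1e-9) n_equal <- n_equal + 1L
  }
  expect_gte(n_equal, 90L)
})

test_that("similarity graph is a valid PSD Laplacian", {
  set.seed(5)
  X <- matrix(rnorm(9 * 30), 9, 30)
  X[, 2] <- X[, 1]                        # identical pair
  g <- build_similarity_graph(X, k_neighbors = 5)
  expect_equal(g$W[1, 2], 1)              # zero distance -> weight 1
  expect_true(Matrix::isSymmetric(g$W))
  expect_true(all(Matrix::diag(g$W) == 0))
  expect_lt(max(abs(Matrix::rowSums(g$laplacian))), 1e-12)
  ev <- eigen(as.matrix(g$laplacian), symmetric = TRUE, only.values = TRUE)
  expect_gte(min(ev$values), -1e-10)

  expect_error(build_similarity_graph(X, k_neighbors = 30), "patches")
  expect_error(build_similarity_graph(X, 5, kernel_sigma = -1), "> 0")
})

test_that("Laplacian energy: trace form equals the weighted double sum", {
  # two nodes, W12 = 1, alpha1 = (1,0), alpha2 = (0,0) -> energy 1
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  L <- diag(rowSums(W)) - W
  G <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(laplacian_energy(G, L), 1.0)
  expect_equal(laplacian_energy(matrix(1, 3, 2),
                                matrix(c(1, -1, -1, 1), 2, 2)),
               0)                          # identical columns -> 0

  set.seed(6)
  for (rep in 1:5) {
    X <- matrix(rnorm(4 * 10), 4, 10)
    g <- build_similarity_graph(X, k_neighbors = 3)
    G <- matrix(rnorm(7 * 10), 7, 10)
    W <- as.matrix(g$W)
    dsum <- 0
    for (i in 1:10) for (j in 1:10)
      dsum <- dsum + W[i, j] * sum((G[, i] - G[, j])^2)
    expect_equal(laplacian_energy(G, g), dsum / 2, tolerance = 1e-10)
  }
})

test_that("Bregman l1 coder: limits, LASSO oracle, monotone objective", {
  D <- init_dictionary(8, 16, method = "random", seed = 3)

  # zero input -> zero codes and splits
  z0 <- sparse_code_bregman(matrix(0, 8, 3), D, n_inner = 5)
  expect_true(all(z0$codes$codes == 0) && all(z0$split$z == 0))

  # large lambda forces near-exact fit (z -> 0); tested in the balanced
  # beta = 1 regime where the split converges cleanly
  set.seed(8)
  x <- matrix(rnorm(8), ncol = 1)
  hi <- sparse_code_bregman(x, D, lambda = 1e4, beta = 1,
                            n_inner = 3000, n_ista = 10)
  expect_lt(max(abs(hi$split$z)), 1e-3)
  ls_fit <- qr.fitted(qr(D$atoms), x)     # least-squares benchmark
  expect_lt(sqrt(sum((D$atoms %*% hi$codes$codes - ls_fit)^2)), 1e-3)

  # mu_graph = 0, single patch: equals the LASSO solution
  # min 1/2 ||x - D a||^2 + (1/lambda) ||a||_1 from an independent
  # coordinate-descent oracle
  lasso_cd <- function(x, D, w, sweeps = 4000) {
    a <- numeric(ncol(D))
    r <- as.vector(x)
    for (s in seq_len(sweeps)) for (j in seq_len(ncol(D))) {
      rho <- sum(D[, j] * r) + a[j]       # unit-norm columns
      aj <- sign(rho) * max(abs(rho) - w, 0)
      r <- r - D[, j] * (aj - a[j])
      a[j] <- aj
    }
    a
  }
  lam <- 2
  sb <- sparse_code_bregman(x, D, lambda = lam, beta = 4,
                            n_inner = 4000, n_ista = 10)
  a_cd <- lasso_cd(x, D$atoms, 1 / lam)
  expect_lt(max(abs(sb$codes$codes[, 1] - a_cd)), 1e-6)

  # objective is monotone nonincreasing per sweep on random instances
  for (sd in 1:3) {
    set.seed(sd)
    X <- matrix(rnorm(8 * 25) * 50, 8, 25)
    g <- build_similarity_graph(X, k_neighbors = 4)
    sc <- sparse_code_bregman(X, D, graph = g, lambda = 1, mu_graph = 0.01,
                              beta = 1, n_inner = 10, n_ista = 5)
    expect_true(all(diff(sc$objective) <= abs(sc$objective[1]) * 1e-9))
  }
})

test_that("dictionary update never increases the fit residual", {
  set.seed(9)
  X <- matrix(rnorm(16 * 32), 16, 32)     # random 16 x 32 instance
  D <- init_dictionary(16, 24, method = "random", seed = 4)
  G <- as.matrix(sparse_code_omp(X, D, 3)$codes)
  r0 <- norm(X - D$atoms %*% G, "F")
  D1 <- update_dictionary(D, X, G)
  expect_lte(norm(X - D1$atoms %*% G, "F"), r0 + 1e-10)
  expect_equal(colSums(D1$atoms^2), rep(1, 24), tolerance = 1e-9)

  # Gamma = 0 with pre-normalized D leaves D unchanged
  D2 <- update_dictionary(D, X, matrix(0, 24, 32))
  expect_equal(D2$atoms, D$atoms, tolerance = 1e-12)
})
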