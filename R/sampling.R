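#' k-space sampling masks
#'
#' Three undersampling trajectories over an M x N k-space grid, all in R's
#' FFT layout (DC at element \[1,1\], frequencies wrapping around): a
#' variable-density random 2D pattern, a Cartesian pattern keeping whole
#' frequency-encode rows, and its phase-encode (column) analogue. The
#' acceleration factor is the ratio of total to acquired samples; the
#' realized factor is stored alongside the request.
#'
#' @name sampling-masks
NULL

new_sampling_mask <- function(mask, trajectory, requested, extra = list()) {
  structure(c(list(mask = mask,
                   factor = length(mask) / sum(mask),
                   requested_factor = requested,
                   trajectory = trajectory), extra),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("<sampling_mask %s %d x %d, factor %.3f (requested %.3f)>\n",
              x$trajectory, nrow(x$mask), ncol(x$mask), x$factor,
              x$requested_factor))
  invisible(x)
}

as_mask_matrix <- function(x) {
  if (inherits(x, "sampling_mask")) return(x$mask)
  if (is.logical(x) && is.matrix(x)) return(x)
  stop("expected a sampling_mask or logical matrix", call. = FALSE)
}

check_factor <- function(shape, factor) {
  if (factor < 1 || factor > min(prod(shape), 20))
    stop("acceleration `factor` must be in [1, min(M*N, 20)]", call. = FALSE)
}

#' Variable-density random 2D mask
#'
#' Samples exactly `floor(M*N/factor)` k-space positions without
#' replacement: a fully sampled low-frequency center block (width
#' `center_fraction` of each axis around DC) is always kept, and the
#' remaining budget is drawn with Gaussian weights decaying with distance
#' from DC, so low frequencies are sampled densely.
#'
#' @param shape integer length-2 (M, N).
#' @param factor requested acceleration in \[1, 20\].
#' @param center_fraction fraction of each axis forced on around DC
#'   (default 0.04).
#' @param seed integer seed.
#' @param density_sigma Gaussian density scale as a fraction of the axis
#'   length (default 1/6).
#' @return a `sampling_mask`.
#' @export
make_random2d_mask <- function(shape, factor, center_fraction = 0.04,
                               seed = 1L, density_sigma = 1 / 6) {
  M <- shape[1]; N <- shape[2]
  check_factor(shape, factor)
  if (center_fraction < 0 || center_fraction >= 1)
    stop("`center_fraction` must be in [0, 1)", call. = FALSE)
  budget <- floor(M * N / factor)
  dr <- freq_dist(M); dc <- freq_dist(N)
  center <- outer(dr <= center_fraction * M / 2,
                  dc <= center_fraction * N / 2, `&`)
  n_center <- sum(center)
  if (n_center > budget)
    stop(sprintf(
      "center block (%d samples) exceeds the sampling budget (%d) at factor %g",
      n_center, budget, factor), call. = FALSE)
  mask <- center
  n_rest <- budget - n_center
  if (n_rest > 0L) {
    w <- exp(-(outer((dr / M)^2, (dc / N)^2, `+`)) / (2 * density_sigma^2))
    cand <- which(!center)
    pick <- with_seed(seed, sample(cand, n_rest, prob = w[cand]))
    mask[pick] <- TRUE
  }
  new_sampling_mask(mask, "random2d", factor,
                    list(center_fraction = center_fraction, seed = seed))
}

line_mask <- function(n_lines, factor, center_lines, seed) {
  n_keep <- max(1L, round(n_lines / factor))
  if (center_lines > n_keep)
    stop(sprintf(
      "center block (%d lines) exceeds the sampling budget (%d lines) at factor %g",
      center_lines, n_keep, factor), call. = FALSE)
  d <- freq_dist(n_lines)
  ord <- order(d, seq_len(n_lines))           # nearest-to-DC first, ties by index
  center <- ord[seq_len(center_lines)]
  rest <- setdiff(seq_len(n_lines), center)
  extra <- if (n_keep > center_lines)
    with_seed(seed, sample(rest, n_keep - center_lines)) else integer(0)
  sort(c(center, extra))
}

#' Cartesian (row-wise) undersampling mask
#'
#' Keeps `round(M/factor)` fully sampled frequency-encode rows:
#' `center_lines` rows nearest DC plus a random subset of the rest.
#'
#' @inheritParams make_random2d_mask
#' @param center_lines number of always-kept central rows (default 4).
#' @export
make_cartesian_mask <- function(shape, factor, center_lines = 4L, seed = 1L) {
  M <- shape[1]; N <- shape[2]
  check_factor(shape, factor)
  keep <- line_mask(M, factor, center_lines, seed)
  mask <- matrix(FALSE, M, N)
  mask[keep, ] <- TRUE
  new_sampling_mask(mask, "cartesian", factor,
                    list(center_lines = center_lines, seed = seed,
                         kept_lines = keep))
}

#' Phase-encode (column-wise) undersampling mask
#'
#' Column analogue of [make_cartesian_mask()]: keeps `round(N/factor)`
#' fully sampled phase-encode columns.
#'
#' @inheritParams make_cartesian_mask
#' @export
make_phase_encode_mask <- function(shape, factor, center_lines = 4L,
                                   seed = 1L) {
  M <- shape[1]; N <- shape[2]
  check_factor(shape, factor)
  keep <- line_mask(N, factor, center_lines, seed)
  mask <- matrix(FALSE, M, N)
  mask[, keep] <- TRUE
  new_sampling_mask(mask, "phase_encode", factor,
                    list(center_lines = center_lines, seed = seed,
                         kept_lines = keep))
}

#' Partial Fourier operator and its adjoint
#'
#' `partial_fourier()` applies F_p u = mask o FFT(u) (orthonormal scaling);
#' `partial_fourier_adjoint()` applies the adjoint, the inverse FFT of the
#' zero-filled data. With unit-modulus FFT scaling F_p^H F_p is the
#' orthogonal projection onto the sampled frequencies.
#'
#' @param image real (or complex) M x N matrix, or a phantom.
#' @param mask a `sampling_mask` or logical matrix of the same shape.
#' @return `partial_fourier()`: a `kspace` object with off-mask entries
#'   zero. `partial_fourier_adjoint()`: a complex M x N matrix.
#' @export
partial_fourier <- function(image, mask) {
  u <- if (inherits(image, "phantom")) image$image else image
  m <- as_mask_matrix(mask)
  if (!all(dim(u) == dim(m))) stop("image/mask shape mismatch", call. = FALSE)
  structure(list(values = fft2c(u) * m), class = "kspace")
}

#' @param kspace a `kspace` object or complex matrix (zero off-mask).
#' @rdname partial_fourier
#' @export
partial_fourier_adjoint <- function(kspace, mask) {
  v <- as_kspace_values(kspace)
  m <- as_mask_matrix(mask)
  if (!all(dim(v) == dim(m))) stop("kspace/mask shape mismatch", call. = FALSE)
  ifft2c(v * m)
}
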