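#' Peak signal-to-noise ratio
#'
#' PSNR = 10 log10(255^2 M N / sum |u - f|^2) in decibels, with the peak
#' fixed at 255 (the reference must be on the \[0, 255\] scale; use
#' [rescale255()] first if it is not). Identical inputs return the +Inf
#' sentinel. PSNR depends on the inputs only through their difference, so
#' adding the same constant to both leaves it unchanged.
#'
#' @param reference ground-truth image (matrix or phantom), \[0, 255\].
#' @param reconstruction image of the same shape.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(reference, reconstruction) {
  u <- as_image(reference)
  f <- as_image(reconstruction)
  if (!all(dim(u) == dim(f))) stop("shape mismatch", call. = FALSE)
  sse <- sum((u - f)^2)
  if (sse == 0) return(Inf)
  10 * log10(255^2 * length(u) / sse)
}

#' Rescale an image linearly to \[0, 255\]
#'
#' @param image numeric matrix.
#' @return matrix with range exactly \[0, 255\] (constant images map to 0).
#' @export
rescale255 <- function(image) {
  u <- as_image(image)
  rng <- range(u)
  if (diff(rng) == 0) return(u * 0)
  (u - rng[1]) / diff(rng) * 255
}

#' PSNR benchmark sweep
#'
#' Full factorial sweep over sampling trajectory, acceleration factor,
#' k-space noise level, reconstruction method and seed on one phantom.
#' Each cell simulates k-space, applies the mask and noise, reconstructs,
#' and scores PSNR against the phantom. Failures in a cell are recorded
#' (status column) and the sweep continues.
#'
#' @param phantom a [make_phantom()] result (or \[0,255\] matrix).
#' @param trajectories subset of `c("random2d", "cartesian", "phase_encode")`.
#' @param factors acceleration factors (the benchmark protocol spans 2.5-20).
#' @param noise_sigmas per-component k-space noise sds.
#' @param methods subset of `c("dictionary", "tv", "zero_fill")`.
#' @param seeds integer vector; one row per seed.
#' @param config [recon_config()] used for the dictionary method (its
#'   `lambda_tv`/`mu`/`n_outer` also parameterize the TV method).
#' @return data.frame of class `benchmark_result` with columns trajectory,
#'   factor, noise_sigma, seed, method, psnr_db, n_iter, status.
#' @export
run_benchmark <- function(phantom,
                          trajectories = "random2d",
                          factors = c(2.5, 4, 8, 20),
                          noise_sigmas = 0,
                          methods = c("dictionary", "tv", "zero_fill"),
                          seeds = 1L,
                          config = recon_config()) {
  stopifnot(all(methods %in% c("dictionary", "tv", "zero_fill")),
            all(trajectories %in% c("random2d", "cartesian", "phase_encode")))
  truth <- as_image(phantom)
  ks_full <- simulate_kspace(truth)
  grid <- expand.grid(trajectory = trajectories, factor = factors,
                      noise_sigma = noise_sigmas, seed = seeds,
                      method = methods, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    out <- data.frame(g, psnr_db = NA_real_, n_iter = NA_integer_,
                      status = "ok", stringsAsFactors = FALSE)
    tryCatch({
      mk <- switch(g$trajectory,
                   random2d = make_random2d_mask(dim(truth), g$factor,
                                                 seed = g$seed),
                   cartesian = make_cartesian_mask(dim(truth), g$factor,
                                                   seed = g$seed),
                   phase_encode = make_phase_encode_mask(dim(truth), g$factor,
                                                         seed = g$seed))
      ks <- add_gaussian_noise(ks_full, g$noise_sigma, seed = g$seed + 1L)
      ks$values <- ks$values * mk$mask
      rec <- switch(g$method,
        zero_fill = {
          out$n_iter <- 0L
          clip01(zero_fill_baseline(ks, mk), 0, 255)
        },
        tv = {
          out$n_iter <- config$n_outer
          reconstruct_tv(ks, mk, lambda_tv = config$lambda_tv,
                         mu = config$mu, n_outer = config$n_outer)
        },
        dictionary = {
          r <- reconstruct(ks, mk, config)
          out$n_iter <- r$state$k
          r$image
        })
      out$psnr_db <- psnr(truth, rec)
    }, error = function(e) out$status <<- conditionMessage(e))
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("benchmark_result", class(res))
  res
}
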