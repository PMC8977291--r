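#' Simulated bowel-wall phantom
#'
#' Builds a piecewise-smooth 2D phantom emulating a dark-lumen colonography
#' slice: a body ellipse containing an annular "bowel wall" around a dark,
#' water-filled lumen, with a smooth seeded background texture and optional
#' elliptical lesions of specified contrast. Intensities are on the
#' \[0, 255\] scale used by the PSNR convention.
#'
#' @param height,width grid size in pixels (each at least 32).
#' @param lesions list of lesion specifications; each element is a list with
#'   fields `center` (row, col in pixels), `radii` (row/col semi-axes in
#'   pixels; a single value means a circle) and `contrast` (additive
#'   intensity change inside the lesion).
#' @param seed integer seed; identical seeds give bitwise-identical phantoms.
#' @param texture_amplitude standard deviation of the smooth random tissue
#'   texture inside the body, in intensity units (default 8, about 5% of
#'   the enhancing-wall signal — tissue-like heterogeneity; 0 disables it).
#' @return an object of class `phantom`: list with `image` (height x width
#'   matrix in \[0,255\]), `lesion_mask` (logical matrix), `lesions`, `seed`.
#' @examples
#' ph <- make_phantom(64, 64, lesions = list(list(center = c(32, 20),
#'                                                radii = 4, contrast = 60)))
#' range(ph$image)
#' @export
make_phantom <- function(height = 128L, width = 128L, lesions = list(),
                         seed = 1L, texture_amplitude = 8) {
  if (height < 32L || width < 32L)
    stop("phantom grid must be at least 32 x 32", call. = FALSE)
  M <- as.integer(height); N <- as.integer(width)

  # normalized coordinates in [-1, 1]
  y <- matrix(seq(-1, 1, length.out = M), M, N)
  x <- matrix(seq(-1, 1, length.out = N), M, N, byrow = TRUE)

  # piecewise-smooth anatomy: nested ellipses painted with a ~1 px soft
  # edge (alpha from the approximate signed distance to the ellipse), so
  # regions are smooth inside but boundaries stay sharp
  layer_alpha <- function(cy, cx, ry, rx, edge_px = 0.8) {
    q <- sqrt(((y - cy) / ry)^2 + ((x - cx) / rx)^2)
    r_eff <- sqrt(ry * rx) * min(M, N) / 2        # px per unit of q
    clip01(0.5 - (q - 1) * r_eff / edge_px, 0, 1)
  }
  img <- matrix(5, M, N)                          # air background
  for (ly in list(list(0.92, 0.88, 60),           # body
                  list(0.62, 0.55, 170),          # enhancing bowel wall
                  list(0.44, 0.38, 20))) {        # dark water-filled lumen
    a <- layer_alpha(0, 0, ly[[1]], ly[[2]])
    img <- (1 - a) * img + a * ly[[3]]
  }

  # smooth seeded texture inside the body: low-pass-filtered white noise
  if (texture_amplitude > 0) {
    tex <- with_seed(seed, matrix(rnorm(M * N), M, N))
    fr <- freq_dist(M) / M
    fc <- freq_dist(N) / N
    lp <- exp(-(outer(fr^2, fc^2, `+`)) / (2 * 0.08^2))  # ~2 px correlation
    tex <- Re(ifft2c(fft2c(tex) * lp))
    tex <- tex / max(1e-12, stats::sd(tex)) * texture_amplitude
    img <- img + tex * layer_alpha(0, 0, 0.92, 0.88)
  }

  lesion_mask <- matrix(FALSE, M, N)
  row_px <- matrix(seq_len(M), M, N)
  col_px <- matrix(seq_len(N), M, N, byrow = TRUE)
  for (k in seq_along(lesions)) {
    ls <- lesions[[k]]
    if (is.null(ls$center) || is.null(ls$radii) || is.null(ls$contrast))
      stop("each lesion needs `center`, `radii` and `contrast`", call. = FALSE)
    r <- rep_len(as.numeric(ls$radii), 2L)
    ct <- as.numeric(ls$center)
    if (ct[1] - r[1] < 1 || ct[1] + r[1] > M || ct[2] - r[2] < 1 || ct[2] + r[2] > N)
      stop(sprintf("lesion %d extends outside the %d x %d grid", k, M, N),
           call. = FALSE)
    m <- ((row_px - ct[1]) / r[1])^2 + ((col_px - ct[2]) / r[2])^2 <= 1
    img[m] <- img[m] + as.numeric(ls$contrast)
    lesion_mask <- lesion_mask | m
  }

  structure(list(image = clip01(img, 0, 255),
                 lesion_mask = lesion_mask,
                 lesions = lesions, seed = as.integer(seed)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %d x %d, %d lesion(s), seed %d>\n",
              nrow(x$image), ncol(x$image), length(x$lesions), x$seed))
  invisible(x)
}

#' Simulate fully sampled k-space from an image
#'
#' Orthonormal 2D discrete Fourier transform of the image; the inverse
#' transform recovers the image to round-off.
#'
#' @param image numeric matrix or a [make_phantom()] result.
#' @return object of class `kspace`: list with complex matrix `values`.
#' @export
simulate_kspace <- function(image) {
  u <- as_image(image)
  if (!all(is.finite(u))) stop("image must be finite", call. = FALSE)
  structure(list(values = fft2c(u)), class = "kspace")
}

#' @export
print.kspace <- function(x, ...) {
  cat(sprintf("<kspace %d x %d>\n", nrow(x$values), ncol(x$values)))
  invisible(x)
}

as_image <- function(x) {
  if (inherits(x, "phantom")) return(x$image)
  if (is.matrix(x)) return(x)
  stop("expected a matrix or a phantom", call. = FALSE)
}

as_kspace_values <- function(x) {
  if (inherits(x, "kspace")) return(x$values)
  if (is.matrix(x)) return(x)
  stop("expected a kspace object or complex matrix", call. = FALSE)
}

#' Add complex Gaussian white noise to k-space data
#'
#' Independent zero-mean Gaussian noise with standard deviation `sigma` is
#' added to the real and imaginary component of every sample, emulating
#' acquisition noise before reconstruction.
#'
#' @param kspace a `kspace` object (or complex matrix).
#' @param sigma per-component noise standard deviation (>= 0).
#' @param seed integer seed for reproducibility.
#' @return a `kspace` object.
#' @export
add_gaussian_noise <- function(kspace, sigma, seed = 1L) {
  stopifnot_scalar(sigma, "sigma")
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  v <- as_kspace_values(kspace)
  if (sigma == 0) return(structure(list(values = v), class = "kspace"))
  n <- length(v)
  noise <- with_seed(seed, complex(real = rnorm(n, sd = sigma),
                                   imaginary = rnorm(n, sd = sigma)))
  structure(list(values = v + matrix(noise, nrow(v), ncol(v))),
            class = "kspace")
}

#' Simulate a diffusion-weighted signal series
#'
#' Mono-exponential decay S(b) = s0 * exp(-ADC * b * 1e-3) with b in s/mm^2
#' and ADC in 1e-3 mm^2/s, with optional additive Gaussian noise.
#'
#' @param s0 signal at b = 0 (> 0).
#' @param adc apparent diffusion coefficient in 1e-3 mm^2/s (> 0).
#' @param b_values strictly increasing diffusion weightings in s/mm^2
#'   (default the acquisition protocol b = 50/400/800).
#' @param sigma noise standard deviation (default 0).
#' @param seed integer seed.
#' @return object of class `dwi_series`: list with `b_values`, `signals`,
#'   `true_adc`, `s0`.
#' @export
simulate_dwi_series <- function(s0, adc, b_values = c(50, 400, 800),
                                sigma = 0, seed = 1L) {
  stopifnot_scalar(s0, "s0", positive = TRUE)
  stopifnot_scalar(adc, "adc", positive = TRUE)
  if (length(b_values) < 2L || any(diff(b_values) <= 0))
    stop("`b_values` must be >= 2 strictly increasing values", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  s <- s0 * exp(-adc * b_values * 1e-3)
  if (sigma > 0)
    s <- s + with_seed(seed, rnorm(length(b_values), sd = sigma))
  structure(list(b_values = as.numeric(b_values), signals = s,
                 true_adc = adc, s0 = s0),
            class = "dwi_series")
}

#' Simulate a contrast-enhancement time-intensity curve
#'
#' Gamma-variate-shaped rise from `baseline` to `peak` followed by washout,
#' on a frame grid defaulting to 30-second intervals after contrast
#' injection. The noiseless curve attains exactly `peak` at `peak_time`
#' (which must be one of `times`).
#'
#' @param baseline pre-enhancement signal (> 0).
#' @param peak peak signal (>= baseline).
#' @param times strictly increasing frame times in seconds.
#' @param peak_time time of peak enhancement; must be in `times` and after
#'   the first frame.
#' @param sigma additive Gaussian noise sd (default 0).
#' @param seed integer seed.
#' @param shape gamma-variate shape parameter (larger = narrower bolus).
#' @return object of class `tic`: list with `times`, `signal`,
#'   `baseline_index` (always 1: the first frame is pre-enhancement).
#' @export
simulate_tic <- function(baseline, peak, times = seq(30, 300, by = 30),
                         peak_time = 120, sigma = 0, seed = 1L, shape = 3) {
  stopifnot_scalar(baseline, "baseline", positive = TRUE)
  stopifnot_scalar(peak, "peak")
  if (peak < baseline) stop("`peak` must be >= `baseline`", call. = FALSE)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("`times` must be >= 2 strictly increasing values", call. = FALSE)
  if (!any(abs(times - peak_time) < 1e-9) || peak_time <= times[1])
    stop("`peak_time` must be one of `times`, after the first frame",
         call. = FALSE)
  t0 <- times[1]
  tp <- peak_time - t0
  tt <- pmax(times - t0, 0)
  g <- ifelse(tt > 0, (tt / tp)^shape * exp(shape * (1 - tt / tp)), 0)
  s <- baseline + (peak - baseline) * g   # g peaks at exactly 1 when tt = tp
  if (sigma > 0) s <- s + with_seed(seed, rnorm(length(s), sd = sigma))
  structure(list(times = as.numeric(times), signal = s, baseline_index = 1L),
            class = "tic")
}

#' Specification of a synthetic two-group diagnostic cohort
#'
#' Defaults state the package's reference cohort design: 98 patients
#' split 49/49 into an algorithm-processed group (ADC 1.55 +/- 0.31
#' 1e-3 mm^2/s, 46/49 diagnosed correctly) and a control group (ADC
#' 0.92 +/- 0.14, 41/49 correct).
#'
#' @param n_per_group patients per group (>= 2).
#' @param adc_mean,adc_sd length-2 numeric: per-group ADC mean and sd, in
#'   1e-3 mm^2/s, order (algorithm, control).
#' @param p_correct length-2 probability of a correct diagnosis per group.
#' @param seed integer seed.
#' @export
cohort_spec <- function(n_per_group = 49L,
                        adc_mean = c(algorithm = 1.55, control = 0.92),
                        adc_sd = c(algorithm = 0.31, control = 0.14),
                        p_correct = c(algorithm = 46 / 49, control = 41 / 49),
                        seed = 1L) {
  if (n_per_group < 2L) stop("`n_per_group` must be >= 2", call. = FALSE)
  if (any(adc_sd <= 0)) stop("`adc_sd` must be > 0", call. = FALSE)
  if (any(p_correct < 0 | p_correct > 1))
    stop("`p_correct` must be in [0, 1]", call. = FALSE)
  structure(list(n_per_group = as.integer(n_per_group),
                 adc_mean = adc_mean, adc_sd = adc_sd,
                 p_correct = p_correct, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a two-group diagnostic cohort
#'
#' Per-group ADC values are Gaussian truncated at zero (redrawn if
#' nonpositive); correctness flags are Bernoulli with the group's
#' `p_correct`.
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` with columns `patient_id`, `group` (factor:
#'   algorithm/control), `adc`, `correct` (0/1).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec",
                                           call. = FALSE)
  n <- spec$n_per_group
  with_seed(spec$seed, {
    draw <- function(mu, sdv) {
      x <- rnorm(n, mu, sdv)
      while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), mu, sdv)
      x
    }
    adc_a <- draw(spec$adc_mean[["algorithm"]], spec$adc_sd[["algorithm"]])
    adc_c <- draw(spec$adc_mean[["control"]], spec$adc_sd[["control"]])
    cor_a <- stats::rbinom(n, 1L, spec$p_correct[["algorithm"]])
    cor_c <- stats::rbinom(n, 1L, spec$p_correct[["control"]])
    data.frame(
      patient_id = sprintf("P%03d", seq_len(2L * n)),
      group = factor(rep(c("algorithm", "control"), each = n),
                     levels = c("algorithm", "control")),
      adc = c(adc_a, adc_c),
      correct = c(cor_a, cor_c))
  })
}
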