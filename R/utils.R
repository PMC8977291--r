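#' @importFrom stats fft rnorm runif sd var pt median quantile
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators never perturb the
# global stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Orthonormal 2D DFT pair: with the 1/sqrt(MN) scaling on both directions
# the transform is unitary, so the masked normal operator F_p^H F_p is an
# orthogonal projection (this is what makes the image update closed-form).
fft2c <- function(u) stats::fft(u) / sqrt(length(u))

ifft2c <- function(f) stats::fft(f, inverse = TRUE) / sqrt(length(f))

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

# Frequency index distance to DC under wrap-around (DC sits at index 1 in
# R's fft layout); used to define "central" k-space.
freq_dist <- function(n) pmin(0:(n - 1L), n - (0:(n - 1L)))

clip01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)
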