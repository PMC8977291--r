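test_that("phantom generation: determinism, lesion handling, intensity range", {
  ph0 <- make_phantom(128, 128, seed = 3)
  expect_false(any(ph0$lesion_mask))
  expect_true(all(ph0$image >= 0 & ph0$image <= 255))

  expect_identical(make_phantom(128, 128, seed = 7)$image,
                   make_phantom(128, 128, seed = 7)$image)
  expect_false(identical(make_phantom(128, 128, seed = 7)$image,
                         make_phantom(128, 128, seed = 8)$image))

  # +60 lesion: mean inside minus mean in a surrounding ring ~ contrast,
  # measured by direct pixel averaging against the lesion geometry.
  # Texture-free phantom first (tight: only edge blending dilutes the
  # boundary), then the textured default (texture sd 8 with ~2 px
  # correlation adds ~2-3 units of local-mean noise to each side).
  ctr <- c(64, 64); rad <- 5
  d <- sqrt(outer((1:128 - ctr[1])^2, (1:128 - ctr[2])^2, `+`))
  ring <- d > rad & d <= rad * 1.6
  ph0t <- make_phantom(128, 128,
                       lesions = list(list(center = ctr, radii = rad,
                                           contrast = 60)),
                       seed = 1, texture_amplitude = 0)
  expect_lt(abs(mean(ph0t$image[ph0t$lesion_mask]) -
                  mean(ph0t$image[ring]) - 60), 3)
  ph <- make_phantom(128, 128,
                     lesions = list(list(center = ctr, radii = rad,
                                         contrast = 60)), seed = 1)
  diff_in_out <- mean(ph$image[ph$lesion_mask]) - mean(ph$image[ring])
  expect_lt(abs(diff_in_out - 60), 10)

  expect_error(make_phantom(64, 64,
                            lesions = list(list(center = c(2, 2), radii = 5,
                                                contrast = 10))),
               "outside")
  expect_error(make_phantom(16, 16), "at least 32")
})

test_that("k-space simulation is a unitary transform", {
  expect_true(all(simulate_kspace(matrix(0, 32, 32))$values == 0))

  ph <- make_phantom(64, 64, seed = 2)
  back <- Re(dlmrc:::ifft2c(simulate_kspace(ph)$values))
  expect_lt(max(abs(back - ph$image)), 1e-10)

  # Parseval on an 8x8 input, both sides as direct double sums
  set.seed(11)
  u <- matrix(rnorm(64), 8, 8)
  ks <- simulate_kspace(u)$values
  e_img <- 0; e_freq <- 0
  for (w in 1:8) for (e in 1:8) {
    e_img <- e_img + u[w, e]^2
    e_freq <- e_freq + Mod(ks[w, e])^2
  }
  expect_equal(e_img, e_freq, tolerance = 1e-12)
})

test_that("k-space noise: seeding, zero-sigma identity, calibrated variance", {
  ks <- simulate_kspace(make_phantom(32, 32, seed = 1))
  expect_identical(add_gaussian_noise(ks, 0, seed = 5)$values, ks$values)
  expect_identical(add_gaussian_noise(ks, 2, seed = 5)$values,
                   add_gaussian_noise(ks, 2, seed = 5)$values)
  expect_error(add_gaussian_noise(ks, -1), ">= 0")

  # empirical per-component variance over ~1e5 draws within 5% of sigma^2
  big <- structure(list(values = matrix(0 + 0i, 320, 320)), class = "kspace")
  nz <- add_gaussian_noise(big, 3, seed = 42)$values
  expect_lt(abs(var(as.vector(Re(nz))) / 9 - 1), 0.05)
  expect_lt(abs(var(as.vector(Im(nz))) / 9 - 1), 0.05)
  expect_lt(abs(mean(Re(nz))), 3 * 3 / 320)
})

test_that("DWI series follows the mono-exponential decay", {
  s <- simulate_dwi_series(1000, 1.5, b_values = c(0, 400, 800))
  expect_equal(s$signals[1], 1000)
  expect_equal(s$signals[3], 1000 * exp(-1.2), tolerance = 1e-12)
  expect_true(all(diff(s$signals) < 0))
  expect_error(simulate_dwi_series(-5, 1), "> 0")
  expect_error(simulate_dwi_series(100, 1, b_values = c(800, 400)),
               "increasing")
  noisy <- simulate_dwi_series(1000, 1.5, sigma = 10, seed = 3)
  expect_identical(noisy$signals,
                   simulate_dwi_series(1000, 1.5, sigma = 10, seed = 3)$signals)
})

test_that("time-intensity curves peak exactly as requested", {
  flat <- simulate_tic(100, 100)
  expect_true(all(flat$signal == 100))

  tc <- simulate_tic(100, 300, times = seq(30, 300, 30), peak_time = 120)
  expect_equal(max(tc$signal), 300, tolerance = 1e-9)
  expect_identical(tc$baseline_index, 1L)
  expect_equal(tc$signal[1], 100)
  expect_identical(simulate_tic(100, 300, sigma = 5, seed = 2)$signal,
                   simulate_tic(100, 300, sigma = 5, seed = 2)$signal)
  expect_error(simulate_tic(100, 300, peak_time = 1234), "peak_time")
})

test_that("cohort simulation matches its specification", {
  tab <- simulate_cohort(cohort_spec(seed = 9))
  expect_equal(nrow(tab), 98L)
  expect_equal(as.vector(table(tab$group)), c(49L, 49L))
  expect_true(all(tab$adc > 0))

  # sample means within 3 sd/sqrt(n) of the stated group means
  m <- tapply(tab$adc, tab$group, mean)
  expect_lt(abs(m[["algorithm"]] - 1.55), 3 * 0.31 / sqrt(49))
  expect_lt(abs(m[["control"]] - 0.92), 3 * 0.14 / sqrt(49))

  all_right <- simulate_cohort(cohort_spec(p_correct = c(algorithm = 1,
                                                         control = 1)))
  expect_true(all(all_right$correct == 1))
  expect_error(cohort_spec(n_per_group = 1), ">= 2")
})
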