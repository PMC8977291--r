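# Shared fixtures, built in code at test time.

default_lesion <- function(M, N, contrast = 60)
  list(list(center = c(M / 2, N * 0.3), radii = M / 16, contrast = contrast))

# small phantom + undersampled noiseless k-space, memoised per geometry
test_problem <- function(M = 64, N = 64, factor = 2.5, seed = 1) {
  ph <- make_phantom(M, N, lesions = default_lesion(M, N), seed = seed)
  ks <- simulate_kspace(ph)
  mk <- make_random2d_mask(c(M, N), factor, seed = seed)
  list(phantom = ph, kspace = ks$values * mk$mask, mask = mk)
}

# complex inner product <a, b> = sum conj(a) b
cdot <- function(a, b) sum(Conj(a) * b)
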