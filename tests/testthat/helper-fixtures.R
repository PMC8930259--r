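# Shared fixtures, all generated in code.

# Uniform-random gray image, deterministic given the seed.
rand_img <- function(h = 16L, w = 16L, seed = 1L, levels = 0:255) {
  set.seed(seed)
  matrix(sample(levels, h * w, replace = TRUE), h, w)
}

# The exactly solvable thresholding fixture: half 10s, half 200s.
half_img <- function(n = 16L) {
  matrix(c(rep(10L, n * n / 2), rep(200L, n * n / 2)), n)
}

# Random label image over classes 0..(k-1).
rand_labels <- function(h = 16L, w = 16L, k = 3L, seed = 1L) {
  set.seed(seed)
  matrix(sample(0:(k - 1L), h * w, replace = TRUE), h, w)
}

# Random antibody as a 0/1 vector.
rand_bits <- function(l = 8L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample(c(0L, 1L), l, replace = TRUE)
}

# Small parameter set for fast unit-test optimizer runs.
quick_params <- function(seed = 1L, ...) {
  immune_params(popsize = 10L, maxgen = 30L, stall_gens = 5L, mc = 5L,
                seed = seed, ...)
}
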