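test_that("pixel assignment is nearest-center with low-index tie-breaks", {
  img5 <- matrix(5L, 1, 1)
  expect_equal(assign_pixels(img5, c(0L, 10L))[1, 1], 0L)  # tie -> lower index
  img <- matrix(c(0L, 255L), 1)
  expect_identical(assign_pixels(img, c(0L, 255L)), matrix(c(0L, 1L), 1))

  # brute-force per-pixel argmin oracle on a random image
  img3 <- rand_img(8, 8, seed = 2)
  centers <- c(40L, 128L, 212L)
  lab <- assign_pixels(img3, centers)
  for (i in seq_len(nrow(img3))) {
    for (j in seq_len(ncol(img3))) {
      d <- (img3[i, j] - centers)^2
      expect_equal(lab[i, j], which.min(d) - 1L)
    }
  }
})

test_that("the clustering objective matches hand evaluation and the least-squares property", {
  img <- matrix(c(0L, 0L, 10L, 10L), 2)
  expect_equal(within_cluster_ss(img, c(0L, 10L)), 0)
  expect_equal(within_cluster_ss(img, c(0L, 8L)), 8)  # 0+0+4+4

  # moving a center to the mean of its pixels never increases J
  for (seed in 1:5) {
    im <- rand_img(8, 8, seed)
    centers <- sort(sample(0:255, 3))
    j0 <- within_cluster_ss(im, centers)
    lab <- assign_pixels(im, centers)
    moved <- centers
    px <- im[lab == 1L]
    if (length(px) > 0) moved[2] <- as.integer(round(mean(px)))
    # exact least-squares mean may be fractional; integer rounding costs < 1/4 per center
    expect_lte(within_cluster_ss(im, moved), j0 + 0.25 * length(centers))
  }
})

test_that("histogram-path J equals the direct per-pixel computation", {
  for (seed in 1:5) {
    im <- rand_img(7, 9, seed)
    centers <- sort(sample(0:255, 4))
    lab <- assign_pixels(im, centers)
    direct <- sum((as.vector(im) - centers[as.vector(lab) + 1L])^2)
    expect_equal(within_cluster_ss(im, centers), direct)
  }
})

test_that("clustering affinities follow their 1/(1+distance) forms", {
  expect_equal(antigen_affinity_ica(0), 1)
  expect_equal(antigen_affinity_ica(8), 1 / 9)
  expect_true(antigen_affinity_ica(3) > antigen_affinity_ica(7))
  expect_error(antigen_affinity_ica(-1), "nonnegative")

  a <- encode_gray(c(0L, 0L))
  b <- encode_gray(c(3L, 4L))
  expect_equal(ab_affinity_euclid(a, b), 1 / 26)  # s = 9 + 16
  expect_equal(ab_affinity_euclid(a, a), 1)
  for (seed in 1:5) {
    x <- encode_gray(sample(0:255, 2)); y <- encode_gray(sample(0:255, 2))
    expect_equal(ab_affinity_euclid(x, y), ab_affinity_euclid(y, x))
  }
})

test_that("Lloyd refinement reproduces the hand-run fixture and descends", {
  img <- matrix(c(0L, 0L, 10L, 10L), 2)
  expect_identical(kmeans_refine(img, c(2L, 8L)), c(0L, 10L))
  expect_equal(within_cluster_ss(img, kmeans_refine(img, c(2L, 8L))), 0)

  # fixed point: centers already at class means stay put
  expect_identical(kmeans_refine(img, c(0L, 10L)), c(0L, 10L))

  # descent up to integer-rounding slack on random images
  for (seed in 1:8) {
    im <- rand_img(12, 12, seed + 20)
    centers <- sort(sample(0:255, 3))
    refined <- kmeans_refine(im, centers)
    expect_lte(within_cluster_ss(im, refined),
               within_cluster_ss(im, centers) + 0.25 * 3)
  }
})

test_that("empty clusters keep their previous centers during refinement", {
  img <- matrix(c(10L, 10L, 12L, 12L), 2)
  refined <- kmeans_refine(img, c(11L, 250L))
  expect_equal(refined[2], 250L)  # nothing assigned to 250; center retained
  expect_equal(refined[1], 11L)
})

test_that("noiseless two-level images cluster to zero J with the true centers", {
  img <- matrix(rep(c(30L, 200L), each = 32), 8)
  res <- ica_segment(img, k = 2,
                     params = immune_params(popsize = 10, maxgen = 25, seed = 5))
  expect_equal(res$j, 0)
  expect_setequal(res$centers, c(30L, 200L))
  sr <- sort_labels_by_center(res)
  expect_identical(sr$centers, c(30L, 200L))
  expect_identical(sr$labels, matrix(as.integer(img == 200L), 8, 8))
})

test_that("K outside [2, 16] is rejected", {
  img <- rand_img(8, 8, 1)
  expect_error(ica_segment(img, k = 1), "\\[2, 16\\]")
  expect_error(ica_segment(img, k = 17), "\\[2, 16\\]")
})

test_that("the reported J is internally consistent and the elite trace never rises", {
  ph <- generate_phantom(24, 24, c(30, 90, 150, 220), noise_sigma = 8, seed = 3)
  res <- ica_segment(ph$image, k = 4,
                     params = immune_params(popsize = 12, maxgen = 40, seed = 3))
  expect_equal(res$j, within_cluster_ss(ph$image, res$centers))
  recomputed <- sum((as.vector(ph$image) -
                       res$centers[as.vector(res$labels) + 1L])^2)
  expect_equal(res$j, recomputed)
  expect_true(all(diff(res$trace$best_objective) <= 0))
  expect_true(all(diff(res$trace$best_affinity) >= 0))
  expect_true(all(as.vector(res$labels) %in% 0:3))
})

test_that("clustering runs are bit-exact reproducible under a fixed seed", {
  ph <- generate_phantom(20, 20, c(40, 120, 210), noise_sigma = 6, seed = 9)
  p <- immune_params(popsize = 12, maxgen = 30, seed = 77)
  r1 <- ica_segment(ph$image, k = 3, params = p)
  r2 <- ica_segment(ph$image, k = 3, params = p)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$centers, r2$centers)
  expect_equal(as.data.frame(r1$trace), as.data.frame(r2$trace))
})

test_that("the hybrid matches an independent multi-restart K-means on a phantom", {
  ph <- generate_phantom(32, 32, c(30, 90, 150, 220), noise_sigma = 8, seed = 11)
  res <- ica_segment(ph$image, k = 4,
                     params = immune_params(popsize = 30, maxgen = 60, seed = 11))
  km <- stats::kmeans(as.vector(ph$image), centers = 4, nstart = 25)
  # integer-constrained centers cost at most ~npix/4 relative to continuous ones
  expect_lte(res$j, km$tot.withinss * 1.02 + length(ph$image) * 0.25)
})
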