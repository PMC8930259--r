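# Synthetic brain-MRI-like phantoms with pixel-level ground truth: nested
# concentric ellipses (background, outer CSF-like ring, inner parenchyma)
# plus an optional hyperintense lesion disc, with additive Gaussian noise.
# These stand in for clinical images so every optimizer and metric is
# testable end to end.

#' Generate a brain-like phantom image with ground truth
#'
#' Geometry: class 0 is the background outside the largest ellipse; classes
#' `1..K-2` (or `1..K-1` without a lesion) are nested concentric ellipses of
#' shrinking size; the last class is an offset lesion disc placed inside the
#' innermost ellipse. Pixel intensity is the class mean plus zero-mean
#' Gaussian noise of scale `noise_sigma`, rounded half up and clipped to
#' \[0, 255\].
#'
#' @param height,width Image size in pixels (>= 8 each for the default
#'   geometry to keep every class nonempty).
#' @param class_means K strictly increasing intensities in \[0, 255\],
#'   K >= 2; the number of classes is `length(class_means)`.
#' @param noise_sigma Additive Gaussian noise scale in gray levels (>= 0).
#' @param lesion Include the lesion disc? Default `TRUE` when K >= 3 (a
#'   lesion needs at least background + tissue + lesion classes).
#' @param lesion_center Optional `(row, col)` of the lesion disc; default
#'   offset down-right of the image center.
#' @param lesion_radius Optional disc radius in pixels; default
#'   `0.12 * min(height, width)`.
#' @param seed RNG seed; the phantom is deterministic given the seed.
#' @return An object of class `phantom`: list with `image` (gray matrix),
#'   `truth` (label matrix, classes `0..K-1`), and `spec` (the arguments).
#' @export
generate_phantom <- function(height = 64L, width = 64L,
                             class_means = c(30, 90, 150, 220),
                             noise_sigma = 8,
                             lesion = length(class_means) >= 3L,
                             lesion_center = NULL, lesion_radius = NULL,
                             seed = 1L) {
  if (!is_count(height, 8L) || !is_count(width, 8L)) {
    stop("`height` and `width` must be integers >= 8", call. = FALSE)
  }
  k <- length(class_means)
  if (k < 2L || any(diff(class_means) <= 0) ||
      any(class_means < 0) || any(class_means > 255)) {
    stop("`class_means` must be >= 2 strictly increasing values in [0, 255]",
         call. = FALSE)
  }
  if (!is.numeric(noise_sigma) || noise_sigma < 0) {
    stop("`noise_sigma` must be >= 0", call. = FALSE)
  }
  if (lesion && k < 3L) {
    stop("a lesion needs at least 3 classes (background, tissue, lesion)",
         call. = FALSE)
  }
  n_struct <- k - as.integer(lesion)  # classes drawn as nested ellipses
  cy <- (height + 1) / 2
  cx <- (width + 1) / 2
  row <- matrix(seq_len(height), height, width)
  col <- matrix(seq_len(width), height, width, byrow = TRUE)

  truth <- matrix(0L, height, width)
  for (j in seq_len(n_struct - 1L)) {
    f <- 0.45 * (n_struct + 1 - j) / n_struct
    inside <- ((col - cx) / (f * width))^2 + ((row - cy) / (f * height))^2 <= 1
    truth[inside] <- j
  }
  if (lesion) {
    r <- if (is.null(lesion_radius)) 0.12 * min(height, width) else lesion_radius
    ctr <- if (is.null(lesion_center)) {
      c(cy + 0.10 * height, cx + 0.08 * width)
    } else lesion_center
    if (ctr[1] - r < 1 || ctr[1] + r > height ||
        ctr[2] - r < 1 || ctr[2] + r > width) {
      stop("lesion disc lies outside the image bounds", call. = FALSE)
    }
    disc <- (row - ctr[1])^2 + (col - ctr[2])^2 <= r^2
    truth[disc] <- k - 1L
  }
  if (any(tabulate(as.vector(truth) + 1L, nbins = k) == 0L)) {
    stop("phantom geometry left a class empty; enlarge the image", call. = FALSE)
  }

  image <- with_seed(seed, {
    v <- class_means[as.vector(truth) + 1L] +
      rnorm(length(truth), 0, noise_sigma)
    matrix(as.integer(pmin(255, pmax(0, round_half_up(v)))), height, width)
  })
  structure(
    list(image = image, truth = truth,
         spec = list(height = height, width = width,
                     class_means = class_means, noise_sigma = noise_sigma,
                     lesion = lesion, seed = seed)),
    class = "phantom")
}

#' Generate a noiseless two-level phantom
#'
#' A random pixel subset of the given fraction is set to `high` (class 1),
#' the rest to `low` (class 0). Useful as an exactly solvable thresholding
#' fixture: with `fraction = 0.5`, `low = 10`, `high = 200` the maximum
#' between-class variance is exactly 9025.
#'
#' @param height,width Image size in pixels.
#' @param low,high Class intensities, `low < high`, both in \[0, 255\].
#' @param fraction Fraction of pixels in the high class, strictly in (0, 1)
#'   and such that both classes are nonempty.
#' @param seed RNG seed for the pixel layout.
#' @return A `phantom` object (see [generate_phantom()]).
#' @export
generate_bilevel <- function(height, width, low = 10L, high = 200L,
                             fraction = 0.5, seed = 1L) {
  if (!is_count(height) || !is_count(width)) {
    stop("`height` and `width` must be positive integers", call. = FALSE)
  }
  if (low >= high || low < 0 || high > 255) {
    stop("need 0 <= low < high <= 255", call. = FALSE)
  }
  npix <- height * width
  n1 <- round_half_up(fraction * npix)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1 ||
      n1 < 1 || n1 > npix - 1) {
    stop("`fraction` must leave both classes nonempty", call. = FALSE)
  }
  truth <- with_seed(seed, {
    m <- matrix(0L, height, width)
    m[sample.int(npix, n1)] <- 1L
    m
  })
  image <- matrix(as.integer(ifelse(truth == 1L, high, low)), height, width)
  structure(
    list(image = image, truth = truth,
         spec = list(height = height, width = width,
                     class_means = c(low, high), noise_sigma = 0,
                     lesion = FALSE, fraction = fraction, seed = seed)),
    class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %dx%d, %d classes (means %s), sigma=%.1f, seed=%d\n",
              x$spec$height, x$spec$width, length(x$spec$class_means),
              paste(x$spec$class_means, collapse = "/"),
              x$spec$noise_sigma, x$spec$seed))
  invisible(x)
}
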