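# Otsu-objective immune thresholding. The "target" class is intensity
# strictly greater than the threshold (lesions are hyperintense on the
# FLAIR/DWI-like images the phantoms emulate); "background" is <= t.

#' Class statistics at a threshold
#'
#' Splits a gray-level histogram at threshold `t` into background
#' (intensity <= t) and target (> t) and returns the class proportions,
#' class mean intensities, and the total mean `V = V0*w0 + V1*w1`.
#' An empty class has mean 0 by convention, which keeps the objective total.
#'
#' @param hist A [gray_histogram()].
#' @param t Threshold gray level in \[0, 255\].
#' @return Named list with `v0`, `w0`, `v1`, `w1`, `v`.
#' @export
class_stats <- function(hist, t) {
  assert_histogram(hist)
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 255) {
    stop("`t` must be a gray level in [0, 255]", call. = FALSE)
  }
  lv <- 0:255
  lower <- lv <= t
  n0 <- sum(hist$counts[lower])
  n1 <- hist$total - n0
  v0 <- n0 / hist$total
  v1 <- n1 / hist$total
  w0 <- if (n0 > 0) sum(hist$counts[lower] * lv[lower]) / n0 else 0
  w1 <- if (n1 > 0) sum(hist$counts[!lower] * lv[!lower]) / n1 else 0
  list(v0 = v0, w0 = w0, v1 = v1, w1 = w1, v = v0 * w0 + v1 * w1)
}

#' Otsu between-class variance at a threshold
#'
#' `V0*(w0 - V)^2 + V1*(w1 - V)^2`, the quantity the immune thresholder
#' maximizes; zero whenever either class is empty. Algebraically equal to
#' `V0*V1*(w0 - w1)^2`.
#'
#' @inheritParams class_stats
#' @return Nonnegative variance.
#' @examples
#' img <- matrix(c(rep(10L, 8), rep(200L, 8)), 4)
#' between_class_variance(gray_histogram(img), 100)  # 9025
#' @export
between_class_variance <- function(hist, t) {
  s <- class_stats(hist, t)
  s$v0 * (s$w0 - s$v)^2 + s$v1 * (s$w1 - s$v)^2
}

# Vectorized variance over all 256 thresholds via cumulative sums.
variance_curve <- function(hist) {
  assert_histogram(hist)
  lv <- 0:255
  cum_n <- cumsum(hist$counts)
  cum_s <- cumsum(hist$counts * lv)
  n <- hist$total
  total_s <- cum_s[256]
  v0 <- cum_n / n
  v1 <- 1 - v0
  w0 <- ifelse(cum_n > 0, cum_s / cum_n, 0)
  w1 <- ifelse(n - cum_n > 0, (total_s - cum_s) / (n - cum_n), 0)
  v <- v0 * w0 + v1 * w1
  v0 * (w0 - v)^2 + v1 * (w1 - v)^2
}

#' Exhaustive Otsu threshold search
#'
#' Evaluates the between-class variance at all 256 thresholds and returns the
#' smallest threshold attaining the maximum. This is the deterministic oracle
#' the immune thresholder is validated against, and the "plain scan" baseline
#' of the benchmark harness.
#'
#' @param hist A [gray_histogram()].
#' @return List with `threshold` and `variance`.
#' @export
exhaustive_otsu <- function(hist) {
  curve <- variance_curve(hist)
  best <- which.max(curve)  # first maximum -> smallest t
  list(threshold = best - 1L, variance = curve[best])
}

#' Immune-search Otsu thresholding
#'
#' Runs the clonal-selection engine over the 8-bit threshold code with the
#' between-class variance as antigen affinity (used raw, not rescaled: the
#' concentration correction is multiplicative, hence scale-covariant) and the
#' stall rule as termination.
#'
#' @param img Integer gray image matrix in \[0, 255\].
#' @param params An [immune_params()]; defaults popsize 20, maxgen 200,
#'   qc 0.6, qm 0.06, lambda 0.95, k -0.8, mc 10, stall 20.
#' @return An object of class `threshold_result`: list with `threshold`,
#'   `variance` (the between-class variance at that threshold), `mask`
#'   (0 = background <= t, 1 = target > t), `generations`, `trace`, `params`.
#' @seealso [exhaustive_otsu()]
#' @export
aia_threshold <- function(img, params = immune_params()) {
  assert_gray_image(img)
  hist <- gray_histogram(img)
  curve <- variance_curve(hist)
  affinity <- function(bits) curve[decode_gray(bits) + 1L]
  fit <- run_immune(affinity, L = 8L, params = params,
                    stop_rule = stop_stall(params$stall_gens),
                    pair_affinity = "hamming")
  t <- decode_gray(fit$bits)
  structure(
    list(threshold = t, variance = fit$objective,
         mask = matrix(as.integer(img > t), nrow(img), ncol(img)),
         generations = fit$generations, trace = fit$trace, params = params),
    class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> t=%d variance=%.4f (%d generations)\n",
              x$threshold, x$variance, x$generations))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.threshold_result <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, variance = x$variance,
                 generations = x$generations,
                 target_fraction = mean(x$mask == 1L))
}

#' @exportS3Method generics::tidy
tidy.threshold_result <- function(x, ...) {
  tibble::as_tibble(x$trace)
}
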