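# Immune clustering: antibodies encode K gray-level cluster centers (8 bits
# each); antigen affinity is 1/(1+J) with J the within-cluster sum of squared
# intensity differences; the clonal-selection global search is hybridized
# with K-means (Lloyd) local refinement of the elite antibody.

assert_centers <- function(centers) {
  k <- length(centers)
  if (k < 2L || k > 16L) stop("need 2 <= K <= 16 cluster centers", call. = FALSE)
  if (anyNA(centers) || any(centers < 0) || any(centers > 255) ||
      any(centers != as.integer(centers))) {
    stop("centers must be integer gray levels in [0, 255]", call. = FALSE)
  }
  invisible(as.integer(centers))
}

#' Assign pixels to the nearest cluster center
#'
#' Each pixel goes to the center minimizing the squared intensity difference;
#' ties go to the lowest center index. Labels are `0..K-1` in center order
#' (the order of `centers`, not sorted).
#'
#' @param img Integer gray image matrix.
#' @param centers Integer vector of K gray-level centers (order = label).
#' @return Integer label matrix with the image's shape.
#' @export
assign_pixels <- function(img, centers) {
  assert_gray_image(img)
  centers <- assert_centers(centers)
  d <- outer(as.vector(img), centers, function(x, c) (x - c)^2)
  lab <- max.col(-d, ties.method = "first") - 1L
  matrix(as.integer(lab), nrow(img), ncol(img))
}

# Per-gray-level nearest-center assignment and J, computed on the histogram
# (exactly equivalent to the per-pixel computation, 256*K work instead of
# npixels*K).
level_assignment <- function(centers) {
  d <- outer(0:255, centers, function(x, c) (x - c)^2)
  list(label = max.col(-d, ties.method = "first") - 1L,
       mind = d[cbind(1:256, max.col(-d, ties.method = "first"))])
}

wss_from_counts <- function(counts, centers) {
  la <- level_assignment(centers)
  sum(counts * la$mind)
}

#' Within-cluster sum of squares
#'
#' The clustering objective J: the sum over pixels of the squared difference
#' between each pixel's intensity and its assigned center (under
#' [assign_pixels()]'s nearest-center rule).
#'
#' @inheritParams assign_pixels
#' @return Nonnegative J.
#' @examples
#' img <- matrix(c(0L, 0L, 10L, 10L), 2)
#' within_cluster_ss(img, c(0L, 8L))  # 8
#' @export
within_cluster_ss <- function(img, centers) {
  assert_gray_image(img)
  centers <- assert_centers(centers)
  wss_from_counts(gray_histogram(img)$counts, centers)
}

#' Antigen affinity of a clustering solution
#'
#' `1 / (1 + J)`: equals 1 iff the fit is perfect (J = 0) and decreases
#' strictly with J.
#'
#' @param j Nonnegative within-cluster sum of squares.
#' @return Affinity in (0, 1\].
#' @export
antigen_affinity_ica <- function(j) {
  if (any(j < 0)) stop("`j` must be nonnegative", call. = FALSE)
  1 / (1 + j)
}

#' Antibody-antibody affinity via Euclidean distance between center sets
#'
#' `1 / (1 + s)` where `s` is the sum over the K positions of squared
#' differences between the two decoded center sets.
#'
#' @param a,b Antibodies of equal length decoding to K centers each.
#' @return Affinity in (0, 1\]; 1 iff the decodings are identical.
#' @export
ab_affinity_euclid <- function(a, b) {
  if (length(a) != length(b)) {
    stop("antibodies must have equal lengths", call. = FALSE)
  }
  ca <- decode_gray(a)
  cb <- decode_gray(b)
  1 / (1 + sum((ca - cb)^2))
}

#' K-means (Lloyd) refinement of gray-level centers
#'
#' Alternates nearest-center assignment and center update (each center moves
#' to the half-up-rounded mean intensity of its assigned pixels; an empty
#' cluster keeps its previous center) until the pixel labeling is unchanged
#' or `max_iter` is reached. Because centers are integer gray levels, J may
#' rise by at most 1/4 per center relative to the real-valued update, but
#' never more.
#'
#' @inheritParams assign_pixels
#' @param max_iter Iteration cap (>= 1). Default 100.
#' @return The refined integer center vector (same length, original order
#'   positions updated in place).
#' @export
kmeans_refine <- function(img, centers, max_iter = 100L) {
  assert_gray_image(img)
  centers <- assert_centers(centers)
  if (!is_count(max_iter)) stop("`max_iter` must be a positive integer", call. = FALSE)
  counts <- gray_histogram(img)$counts
  refine_centers_hist(counts, centers, max_iter)
}

refine_centers_hist <- function(counts, centers, max_iter) {
  lv <- 0:255
  occupied <- counts > 0
  prev_label <- NULL
  for (it in seq_len(max_iter)) {
    la <- level_assignment(centers)
    lab_occ <- la$label[occupied]
    if (!is.null(prev_label) && identical(lab_occ, prev_label)) break
    prev_label <- lab_occ
    for (j in seq_along(centers)) {
      sel <- occupied & la$label == j - 1L
      if (any(sel)) {
        centers[j] <- as.integer(round_half_up(
          sum(counts[sel] * lv[sel]) / sum(counts[sel])))
      }
    }
  }
  as.integer(centers)
}

#' Immune clustering segmentation
#'
#' Clonal-selection search over K encoded gray-level centers, hybridized with
#' K-means: every generation the elite (memory-cell) antibody is decoded,
#' Lloyd-refined, re-encoded, and adopted if its objective improves. Antibody
#' crowding is measured by Euclidean affinity between decoded center sets.
#' The run stops at `maxgen`, or early by the `|J1 - J*|` rule: while the
#' elite objective `J*` stays within `j_tol` (default `1e-3 * J1`) of the
#' first-generation elite objective `J1` the problem is treated as
#' degenerate or already solved and the run ends; otherwise the full budget
#' is used (see [stop_objective_delta()]).
#'
#' @param img Integer gray image matrix in \[0, 255\].
#' @param k Number of clusters, `2 <= k <= 16`. Default 4 (background,
#'   CSF-like, parenchyma-like, lesion-like phantom classes).
#' @param params An [immune_params()]; when omitted the clustering defaults
#'   popsize 30, maxgen 300 are used.
#' @param refine_iter Lloyd iteration cap for the per-generation elite
#'   refinement. Default 100.
#' @return An object of class `ica_result`: list with `labels` (pixel labels
#'   `0..k-1` in encoded-center order), `centers`, `j` (final objective,
#'   equal to the within-cluster sum of squares recomputed from labels and
#'   centers), `j1` (first-generation elite objective), `generations`,
#'   `trace`, `params`, `k`.
#' @export
ica_segment <- function(img, k = 4L, params = NULL, refine_iter = 100L) {
  assert_gray_image(img)
  if (!is_count(k, 2L) || k > 16L) {
    stop("`k` must be an integer in [2, 16]", call. = FALSE)
  }
  if (is.null(params)) params <- immune_params(popsize = 30L, maxgen = 300L)
  if (!inherits(params, "immune_params")) {
    stop("`params` must be an immune_params object", call. = FALSE)
  }
  k <- as.integer(k)
  counts <- gray_histogram(img)$counts
  objective <- function(bits) wss_from_counts(counts, decode_gray(bits))
  affinity <- function(bits) antigen_affinity_ica(objective(bits))
  refine <- function(bits) {
    encode_gray(refine_centers_hist(counts, decode_gray(bits), refine_iter))
  }
  fit <- run_immune(affinity, L = 8L * k, params = params,
                    stop_rule = stop_objective_delta(params$j_tol),
                    pair_affinity = "euclid",
                    objective = objective, refine = refine)
  centers <- decode_gray(fit$bits)
  labels <- assign_pixels(img, centers)
  structure(
    list(labels = labels, centers = centers,
         j = within_cluster_ss(img, centers), j1 = fit$initial_objective,
         generations = fit$generations, trace = fit$trace,
         params = params, k = k),
    class = "ica_result")
}

#' Relabel a clustering so labels follow ascending center intensity
#'
#' Cluster labels come out in encoded-center order; for evaluation against
#' ground truth whose classes are ordered by mean intensity, relabel so that
#' label 0 is the darkest center, label `K-1` the brightest. Ties keep
#' encoded order.
#'
#' @param result An `ica_result`.
#' @return The result with `labels` and `centers` reordered ascending.
#' @export
sort_labels_by_center <- function(result) {
  if (!inherits(result, "ica_result")) {
    stop("`result` must be an ica_result", call. = FALSE)
  }
  ord <- order(result$centers)        # stable for ties
  new_of_old <- integer(result$k)
  new_of_old[ord] <- seq_len(result$k) - 1L
  result$labels <- matrix(new_of_old[result$labels + 1L],
                          nrow(result$labels), ncol(result$labels))
  result$centers <- result$centers[ord]
  result
}

#' @export
print.ica_result <- function(x, ...) {
  cat(sprintf("<ica_result> K=%d centers=[%s] J=%.4f J1=%.4f (%d generations)\n",
              x$k, paste(x$centers, collapse = ", "), x$j, x$j1, x$generations))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.ica_result <- function(x, ...) {
  tibble::tibble(k = x$k, j = x$j, j1 = x$j1, generations = x$generations)
}

#' @exportS3Method generics::tidy
tidy.ica_result <- function(x, ...) {
  tibble::tibble(cluster = seq_len(x$k) - 1L, center = x$centers,
                 size = as.integer(tabulate(as.vector(x$labels) + 1L,
                                            nbins = x$k)))
}
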