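# Benchmark harness: sweep the number of divisions K over replicate
# phantoms and compare the exhaustive-Otsu baseline, the immune thresholder,
# and the immune clusterer on the volume-fraction metrics.

#' Benchmark segmentation algorithms on replicate phantoms
#'
#' For each K (number of divisions, read as the number of segmentation
#' classes), each replicate phantom, and each algorithm, the harness
#' generates a phantom with K evenly spread class means, segments it, and
#' evaluates against the ground truth. Thresholding arms produce binary
#' masks, so on phantoms with K > 2 their metrics for the upper classes
#' degrade by construction; the clustering arm fits all K classes.
#'
#' @param k_values Integer vector of class counts to sweep (each >= 2).
#' @param n_replicates Replicate phantoms per K (>= 1).
#' @param seeds Optional matrix-free seed vector of length `n_replicates`;
#'   default `seq_len(n_replicates) + 1000`. Replicate r of every K reuses
#'   `seeds[r]` for the phantom and both optimizers, so every row is
#'   reproducible from its recorded seed.
#' @param algorithms Subset of `c("otsu", "aia", "ica")`.
#' @param height,width Phantom size. Default 32 x 32.
#' @param noise_sigma Phantom noise scale. Default 8.
#' @param aia_params,ica_params Base [immune_params()] for the two immune
#'   arms (their `seed` is replaced per replicate).
#' @return A tibble of class `benchmark_result`, one row per
#'   algorithm x K x replicate x class: columns algorithm, k, replicate,
#'   seed, class, pr, tpvf, fnvf, fpvf, objective (final J or variance),
#'   generations, error (NA unless that stage failed).
#' @seealso [summarize_benchmark()]
#' @export
benchmark_phantoms <- function(k_values = c(2L, 3L, 4L),
                               n_replicates = 3L,
                               seeds = NULL,
                               algorithms = c("otsu", "aia", "ica"),
                               height = 32L, width = 32L, noise_sigma = 8,
                               aia_params = immune_params(),
                               ica_params = immune_params(popsize = 30L,
                                                          maxgen = 300L)) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  if (!is_count(n_replicates)) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (any(k_values < 2L)) stop("every K must be >= 2", call. = FALSE)
  if (is.null(seeds)) seeds <- seq_len(n_replicates) + 1000L
  if (length(seeds) != n_replicates) {
    stop("`seeds` must have one seed per replicate", call. = FALSE)
  }

  grid <- tidyr::expand_grid(k = as.integer(k_values),
                             replicate = seq_len(n_replicates))
  rows <- purrr::pmap(grid, function(k, replicate) {
    seed <- as.integer(seeds[replicate])
    means <- round_half_up(seq(30, 220, length.out = k))
    ph <- generate_phantom(height, width, class_means = means,
                           noise_sigma = noise_sigma,
                           lesion = k >= 3L, seed = seed)
    purrr::map(algorithms, function(alg) {
      run_benchmark_arm(alg, ph, k, replicate, seed,
                        aia_params, ica_params)
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("benchmark_result", class(out))
  out
}

run_benchmark_arm <- function(alg, ph, k, replicate, seed,
                              aia_params, ica_params) {
  base <- tibble::tibble(algorithm = alg, k = k, replicate = replicate,
                         seed = seed)
  tryCatch({
    res <- switch(alg,
      otsu = {
        o <- exhaustive_otsu(gray_histogram(ph$image))
        list(pred = matrix(as.integer(ph$image > o$threshold),
                           nrow(ph$image), ncol(ph$image)),
             objective = o$variance, generations = NA_integer_)
      },
      aia = {
        p <- aia_params; p$seed <- seed
        r <- aia_threshold(ph$image, p)
        list(pred = r$mask, objective = r$variance,
             generations = r$generations)
      },
      ica = {
        p <- ica_params; p$seed <- seed
        r <- sort_labels_by_center(ica_segment(ph$image, k = k, params = p))
        list(pred = r$labels, objective = r$j, generations = r$generations)
      })
    report <- evaluate_segmentation(res$pred, ph$truth)
    per_class <- report$per_class[, c("class", "pr", "tpvf", "fnvf", "fpvf")]
    dplyr::mutate(
      dplyr::bind_cols(base[rep(1L, nrow(per_class)), ], per_class),
      objective = res$objective,
      generations = res$generations,
      error = NA_character_)
  }, error = function(e) {
    dplyr::mutate(base, class = NA_integer_, pr = NA_real_, tpvf = NA_real_,
                  fnvf = NA_real_, fpvf = NA_real_, objective = NA_real_,
                  generations = NA_integer_, error = conditionMessage(e))
  })
}

#' Summarize a benchmark run
#'
#' Mean and standard deviation of each metric per algorithm x K. Per-class
#' rows within a replicate are first macro-averaged (over defined values),
#' then summarized across replicates.
#'
#' @param results A tibble from [benchmark_phantoms()].
#' @return A tibble with one row per algorithm x K: columns algorithm, k,
#'   n_replicates, and mean/sd of pr, tpvf, fnvf, fpvf.
#' @export
summarize_benchmark <- function(results) {
  macro <- results |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$algorithm, .data$k, .data$replicate) |>
    dplyr::summarise(dplyr::across(c("pr", "tpvf", "fnvf", "fpvf"),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  macro |>
    dplyr::group_by(.data$algorithm, .data$k) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      dplyr::across(c("pr", "tpvf", "fnvf", "fpvf"),
                    list(mean = ~ mean(.x, na.rm = TRUE),
                         sd = ~ stats::sd(.x))),
      .groups = "drop")
}
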