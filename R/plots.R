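# ggplot2 views of the package's result objects.

#' @exportS3Method ggplot2::autoplot
autoplot.immune_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("best_affinity", "best_objective",
                                     "mean_concentration"),
                            names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "generation", y = NULL,
                  title = "Immune-optimizer convergence")
}

#' @exportS3Method ggplot2::autoplot
autoplot.phantom <- function(object, which = c("image", "truth"), ...) {
  which <- match.arg(which)
  m <- object[[which]]
  df <- tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("phantom %s", which), x = NULL, y = NULL)
  if (which == "image") {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   limits = c(0, 255), name = "gray")
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$value))) +
      ggplot2::scale_fill_viridis_d(name = "class")
  }
}

#' @exportS3Method ggplot2::autoplot
autoplot.metric_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_class,
                            cols = c("pr", "tpvf", "fnvf", "fpvf"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$class), y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "class", y = "value",
                  title = "Per-class segmentation metrics")
}

#' Plot benchmark metrics against the number of divisions
#'
#' Mirrors the metrics-versus-divisions comparison: one panel per metric,
#' mean over replicates per algorithm and K, with one line per algorithm.
#'
#' @param results A tibble from [benchmark_phantoms()].
#' @return A ggplot object.
#' @export
plot_benchmark <- function(results) {
  s <- summarize_benchmark(results)
  df <- tidyr::pivot_longer(
    s, cols = dplyr::ends_with("_mean"),
    names_to = "metric", values_to = "mean") |>
    dplyr::mutate(metric = sub("_mean$", "", .data$metric))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$mean,
                                   colour = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "number of divisions (K)", y = "mean over replicates",
                  title = "Segmentation metrics vs number of divisions")
}
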