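# Volume-fraction evaluation of a predicted label image against ground
# truth, one-vs-rest per class: TPVF and FNVF are normalized by the truth
# volume, FPVF by the truth-complement volume, and PR (precision rate) is
# the positive predictive value TP/(TP+FP). Empty denominators yield NA
# ("reported missing"), never a silent zero.

#' One-vs-rest confusion counts for a class
#'
#' @param pred,truth Integer label matrices of the same shape.
#' @param cls Class id to compare one-vs-rest.
#' @return Named integer vector with `tp`, `fp`, `fn`, `tn`
#'   (summing to the pixel count).
#' @export
confusion <- function(pred, truth, cls) {
  assert_same_shape(pred, truth)
  p <- pred == cls
  t <- truth == cls
  c(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t), tn = sum(!p & !t))
}

metric_or_na <- function(num, den) {
  if (den == 0L) NA_real_ else num / den
}

#' Volume-fraction metrics and precision rate
#'
#' `tpvf = TP/(TP+FN)`, `fnvf = FN/(TP+FN)`, `fpvf = FP/(FP+TN)`,
#' `precision_rate = TP/(TP+FP)`. An empty denominator (e.g. an empty truth
#' class for TPVF/FNVF) returns `NA`.
#'
#' @param counts Confusion counts from [confusion()] (named vector with
#'   `tp`, `fp`, `fn`, `tn`).
#' @return A single metric value in \[0, 1\] or `NA`.
#' @name volume_fractions
NULL

#' @rdname volume_fractions
#' @export
tpvf <- function(counts) metric_or_na(counts[["tp"]], counts[["tp"]] + counts[["fn"]])

#' @rdname volume_fractions
#' @export
fnvf <- function(counts) metric_or_na(counts[["fn"]], counts[["tp"]] + counts[["fn"]])

#' @rdname volume_fractions
#' @export
fpvf <- function(counts) metric_or_na(counts[["fp"]], counts[["fp"]] + counts[["tn"]])

#' @rdname volume_fractions
#' @export
precision_rate <- function(counts) metric_or_na(counts[["tp"]], counts[["tp"]] + counts[["fp"]])

# Greedy maximum-overlap matching of predicted labels onto truth classes.
best_match_labels <- function(pred, truth, classes) {
  pred_labels <- sort(unique(as.vector(pred)))
  tab <- table(factor(as.vector(pred), levels = pred_labels),
               factor(as.vector(truth), levels = classes))
  mapping <- stats::setNames(pred_labels, pred_labels)  # identity fallback
  tab_work <- tab
  repeat {
    if (all(tab_work < 0) || nrow(tab_work) == 0L || ncol(tab_work) == 0L) break
    idx <- arrayInd(which.max(tab_work), dim(tab_work))
    if (tab_work[idx] < 0) break
    from <- as.integer(rownames(tab_work)[idx[1]])
    to <- as.integer(colnames(tab_work)[idx[2]])
    mapping[as.character(from)] <- to
    tab_work[idx[1], ] <- -1L
    tab_work[, idx[2]] <- -1L
  }
  matrix(mapping[as.character(as.vector(pred))], nrow(pred), ncol(pred))
}

#' Evaluate a segmentation against ground truth
#'
#' Computes one-vs-rest confusion counts and PR/TPVF/FNVF/FPVF for every
#' truth class, plus macro-averages over the classes where each metric is
#' defined. By default labels are compared as-is (use
#' [sort_labels_by_center()] first for clustering output); with
#' `match = "best"` predicted labels are first greedily re-mapped to the
#' truth classes by maximum overlap.
#'
#' @param pred,truth Integer label matrices of the same shape.
#' @param classes Truth class ids to evaluate; default all classes present
#'   in `truth`.
#' @param match `"none"` (default) or `"best"` (greedy maximum-overlap label
#'   matching before evaluation).
#' @return An object of class `metric_report`: list with `per_class` (tibble:
#'   class, tp, fp, fn, tn, pr, tpvf, fnvf, fpvf) and `macro` (one-row tibble
#'   of means over defined values). `tidy()` returns `per_class`; `glance()`
#'   returns `macro`.
#' @export
evaluate_segmentation <- function(pred, truth,
                                  classes = sort(unique(as.vector(truth))),
                                  match = c("none", "best")) {
  assert_same_shape(pred, truth)
  match <- match.arg(match)
  if (match == "best") pred <- best_match_labels(pred, truth, classes)
  rows <- purrr::map(classes, function(cls) {
    cc <- confusion(pred, truth, cls)
    tibble::tibble(class = cls, tp = cc[["tp"]], fp = cc[["fp"]],
                   fn = cc[["fn"]], tn = cc[["tn"]],
                   pr = precision_rate(cc), tpvf = tpvf(cc),
                   fnvf = fnvf(cc), fpvf = fpvf(cc))
  })
  per_class <- dplyr::bind_rows(rows)
  macro <- dplyr::summarise(
    per_class,
    pr = mean(.data$pr, na.rm = TRUE),
    tpvf = mean(.data$tpvf, na.rm = TRUE),
    fnvf = mean(.data$fnvf, na.rm = TRUE),
    fpvf = mean(.data$fpvf, na.rm = TRUE))
  structure(list(per_class = per_class, macro = macro),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  print(x$per_class)
  cat("macro: ")
  cat(sprintf("PR=%.4f TPVF=%.4f FNVF=%.4f FPVF=%.4f\n",
              x$macro$pr, x$macro$tpvf, x$macro$fnvf, x$macro$fpvf))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.metric_report <- function(x, ...) x$per_class

#' @exportS3Method generics::glance
glance.metric_report <- function(x, ...) x$macro

#' Write a metric report to CSV
#'
#' Columns: class, TP, FP, FN, TN, PR, TPVF, FNVF, FPVF.
#'
#' @param report A `metric_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  df <- as.data.frame(report$per_class)
  names(df) <- c("class", "TP", "FP", "FN", "TN", "PR", "TPVF", "FNVF", "FPVF")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
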