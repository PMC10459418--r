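#' Confusion matrices
#'
#' A `confusion_matrix` is a square integer count matrix over an ordered
#' label set, rows = true class, columns = predicted class. Per-class true
#' positives are the diagonal, false negatives the off-diagonal row sums,
#' false positives the off-diagonal column sums. All downstream machinery
#' (fold aggregation, hierarchical projection, macro metrics, the
#' similar-class grouping algorithm) consumes this type.
#'
#' @name confusion-matrix
NULL

new_confusion_matrix <- function(counts, labels) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(truth = labels, prediction = labels)
  structure(counts, class = c("confusion_matrix", "matrix", "array"))
}

#' Construct a confusion matrix from a count matrix
#'
#' @param counts Square non-negative integer matrix, rows = true class.
#' @param labels Ordered character vector of class labels, one per row.
#' @return A `confusion_matrix`.
#' @export
confusion_matrix <- function(counts, labels = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(labels)) stop("labels are required when `counts` has no rownames")
  labels <- as.character(labels)
  if (nrow(counts) != ncol(counts)) stop("`counts` must be square")
  if (length(labels) != nrow(counts)) stop("length(labels) must match nrow(counts)")
  if (anyDuplicated(labels)) stop("duplicate labels: ",
    paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be non-negative integers")
  }
  new_confusion_matrix(counts, labels)
}

#' Tally a confusion matrix from truth/prediction vectors
#'
#' Counts `(true = i, predicted = j)` pairs over an ordered label set.
#' Labels absent from `labels` in either vector are an error; labels
#' default to the sorted union of the two vectors.
#'
#' @param truth,prediction Equal-length vectors of class labels.
#' @param labels Ordered label set; default the lexicographically sorted
#'   union of observed labels.
#' @return A `confusion_matrix` with `length(labels)` rows.
#' @examples
#' build_cm(c("A", "A", "B"), c("A", "B", "B"))
#' @export
build_cm <- function(truth, prediction, labels = NULL) {
  truth <- as.character(truth)
  prediction <- as.character(prediction)
  if (length(truth) != length(prediction)) {
    stop("`truth` and `prediction` must have equal length")
  }
  if (is.null(labels)) {
    labels <- sort(unique(c(truth, prediction)))
  } else {
    labels <- as.character(labels)
    bad <- setdiff(unique(c(truth, prediction)), labels)
    if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  }
  tf <- factor(truth, levels = labels)
  pf <- factor(prediction, levels = labels)
  new_confusion_matrix(unclass(table(tf, pf)), labels)
}

cm_labels <- function(cm) rownames(unclass(cm))

cm_total <- function(cm) sum(unclass(cm))

#' Aggregate per-fold confusion matrices
#'
#' Element-wise sum of confusion matrices sharing one ordered label set,
#' the operation that turns the five per-fold matrices of a 5-fold
#' cross-validation into the cross-validated confusion matrix (CVCM).
#'
#' @param cms List of `confusion_matrix` objects with identical labels.
#' @return A `confusion_matrix`; its total is the sum of the fold totals.
#' @export
aggregate_folds <- function(cms) {
  stopifnot(is.list(cms), length(cms) >= 1)
  labs <- cm_labels(cms[[1]])
  for (cm in cms[-1]) {
    if (!identical(cm_labels(cm), labs)) {
      d <- union(setdiff(cm_labels(cm), labs), setdiff(labs, cm_labels(cm)))
      stop("fold label sets differ; symmetric difference: ",
        paste(d, collapse = ", "))
    }
  }
  total <- Reduce(`+`, lapply(cms, unclass))
  new_confusion_matrix(total, labs)
}

#' Fine-to-coarse label maps
#'
#' Maps every fine label (a drug name) to exactly one coarse label (its
#' package type, or its similarity group). Used to project a fine-level
#' confusion matrix to the coarse level.
#'
#' @param fine Character vector of fine labels (no duplicates).
#' @param coarse Character vector of coarse labels, one per fine label.
#' @return A named character vector of class `label_map` (names = fine).
#' @export
label_map <- function(fine, coarse) {
  fine <- as.character(fine)
  coarse <- as.character(coarse)
  stopifnot(length(fine) == length(coarse))
  if (anyDuplicated(fine)) {
    stop("fine label mapped more than once: ",
      paste(unique(fine[duplicated(fine)]), collapse = ", "))
  }
  structure(stats::setNames(coarse, fine), class = "label_map")
}

as_label_map <- function(x) {
  if (inherits(x, "label_map")) return(x)
  if (is.data.frame(x)) return(label_map(x[[1]], x[[2]]))
  if (!is.null(names(x))) return(label_map(names(x), unname(x)))
  stop("cannot interpret `x` as a label map")
}

#' Project a fine-level confusion matrix to a coarse level
#'
#' Sums fine-level cells into coarse-level cells under a fine-to-coarse
#' label map. Confusions between fine classes sharing a coarse class land
#' on the coarse diagonal, so coarse accuracy is never below fine accuracy;
#' the total count is conserved.
#'
#' @param cm A fine-level `confusion_matrix`.
#' @param map A [label_map()] (or coercible named vector / two-column data
#'   frame) covering every label of `cm`.
#' @return A coarse-level `confusion_matrix` with lexicographically ordered
#'   coarse labels.
#' @export
project_cm <- function(cm, map) {
  map <- as_label_map(map)
  labs <- cm_labels(cm)
  missing <- setdiff(labs, names(map))
  if (length(missing)) {
    stop("unmapped label(s): ", paste(missing, collapse = ", "))
  }
  coarse_of <- unname(unclass(map)[labs])
  coarse_labs <- sort(unique(coarse_of))
  idx <- match(coarse_of, coarse_labs)
  m <- unclass(cm)
  agg <- matrix(0L, length(coarse_labs), length(coarse_labs))
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      agg[idx[i], idx[j]] <- agg[idx[i], idx[j]] + m[i, j]
    }
  }
  new_confusion_matrix(agg, coarse_labs)
}

#' Macro-averaged classification metrics
#'
#' Computes per-class recall `TP / (TP + FN)`, precision `TP / (TP + FP)`
#' and F1, their unweighted macro averages, and overall accuracy
#' `sum(TP) / total` from a confusion matrix. A class with zero support
#' (recall undefined) or zero predictions (precision undefined) contributes
#' 0 to the macro average, with a warning; macro-F1 is the harmonic mean of
#' macro-precision and macro-recall.
#'
#' @param cm A `confusion_matrix` with positive total.
#' @return A `metrics_report`: list with `macro_recall`, `macro_precision`,
#'   `macro_f1`, `accuracy` (fractions in `[0, 1]`) and `per_class`, a
#'   tibble of class, support, tp, recall, precision and f1.
#' @export
macro_metrics <- function(cm) {
  m <- unclass(cm)
  if (sum(m) == 0) stop("empty confusion matrix")
  labs <- cm_labels(cm)
  tp <- diag(m)
  row_sum <- rowSums(m)
  col_sum <- colSums(m)
  zero_support <- row_sum == 0
  zero_pred <- col_sum == 0
  if (any(zero_support)) {
    warning("zero-support class(es) contribute 0 to macro recall: ",
      paste(labs[zero_support], collapse = ", "))
  }
  if (any(zero_pred)) {
    warning("never-predicted class(es) contribute 0 to macro precision: ",
      paste(labs[zero_pred], collapse = ", "))
  }
  recall <- ifelse(zero_support, 0, tp / row_sum)
  precision <- ifelse(zero_pred, 0, tp / col_sum)
  f1 <- ifelse(precision + recall == 0, 0,
    2 * precision * recall / (precision + recall))
  macro_r <- mean(recall)
  macro_p <- mean(precision)
  macro_f1 <- if (macro_p + macro_r == 0) 0 else {
    2 * macro_p * macro_r / (macro_p + macro_r)
  }
  structure(
    list(
      macro_recall = macro_r,
      macro_precision = macro_p,
      macro_f1 = macro_f1,
      accuracy = sum(tp) / sum(m),
      per_class = tibble::tibble(
        class = labs,
        support = as.integer(row_sum),
        tp = as.integer(tp),
        recall = unname(recall),
        precision = unname(precision),
        f1 = unname(f1)
      )
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report>  accuracy %.4f | macro R %.4f  P %.4f  F1 %.4f  (%d classes)\n",
    x$accuracy, x$macro_recall, x$macro_precision, x$macro_f1,
    nrow(x$per_class)
  ))
  invisible(x)
}

#' Tidy and summarise metric reports
#'
#' `tidy()` returns the per-class table; `glance()` a one-row tibble of the
#' macro-averaged metrics and accuracy.
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy glance
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @rdname tidy.metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    macro_recall = x$macro_recall,
    macro_precision = x$macro_precision,
    macro_f1 = x$macro_f1,
    n_classes = nrow(x$per_class)
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d classes, %d observations\n",
    nrow(unclass(x)), cm_total(x)))
  print(unclass(x))
  invisible(x)
}

#' Tidy a confusion matrix into long form
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return Tibble with columns truth, prediction, n.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  m <- unclass(x)
  labs <- rownames(m)
  tibble::tibble(
    truth = rep(labs, times = ncol(m)),
    prediction = rep(labs, each = nrow(m)),
    n = as.integer(as.vector(m))
  )
}

#' Heat-tile plot of a confusion matrix
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy(object)
  df$truth <- factor(df$truth, levels = rev(cm_labels(object)))
  df$prediction <- factor(df$prediction, levels = cm_labels(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
      fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$n > 0, .data$n, "")),
      size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "predicted", y = "true", fill = "count") +
    ggplot2::theme_minimal()
}

#' Serialize confusion matrices as TSV
#'
#' Writes a tab-separated table whose first column (`label`) holds the
#' ordered labels and whose remaining integer columns are the predicted
#' classes in the same order. The round trip is exact.
#'
#' @param cm A `confusion_matrix`.
#' @param path File path.
#' @return `read_cm` returns a `confusion_matrix`; `write_cm` returns
#'   `path` invisibly.
#' @export
write_cm <- function(cm, path) {
  m <- unclass(cm)
  df <- data.frame(label = rownames(m), m, check.names = FALSE,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cm
#' @export
read_cm <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
    colClasses = "character")
  labels <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  if (!identical(colnames(m), labels)) {
    stop("column labels do not match row labels in ", path)
  }
  confusion_matrix(m, labels)
}

#' Serialize metric reports as JSON
#'
#' Fixed key names: `macro_recall`, `macro_precision`, `macro_f1`,
#' `accuracy`, `per_class`. Values are stored at full precision.
#'
#' @param report A `metrics_report`.
#' @param path File path.
#' @return `read_metrics` returns a `metrics_report`; `write_metrics`
#'   returns `path` invisibly.
#' @export
write_metrics <- function(report, path) {
  payload <- list(
    macro_recall = report$macro_recall,
    macro_precision = report$macro_precision,
    macro_f1 = report$macro_f1,
    accuracy = report$accuracy,
    per_class = report$per_class
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      macro_recall = x$macro_recall,
      macro_precision = x$macro_precision,
      macro_f1 = x$macro_f1,
      accuracy = x$accuracy,
      per_class = tibble::as_tibble(x$per_class)
    ),
    class = "metrics_report"
  )
}
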