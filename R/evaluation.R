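# Confusion-matrix metrics: per-class precision/recall/F1, overall accuracy,
# and first-level group aggregation.

#' Confusion matrix of two label maps
#'
#' `counts[t, p]` = number of pixels with truth class `t` predicted as `p`.
#' Unlabeled truth pixels (id 0) are excluded; a prediction id outside the
#' scheme is an error.
#'
#' @param truth,predicted [label_map()]s (or integer matrices) of equal
#'   size. When `truth` is a `label_map` its scheme fixes the class count.
#' @param n_classes class count when both arguments are bare matrices.
#' @return `C x C` integer matrix with class names on both axes.
#' @export
confusion_matrix <- function(truth, predicted, n_classes = NULL) {
  scheme <- NULL
  if (inherits(truth, "label_map")) {
    scheme <- truth$scheme
    n_classes <- n_classes(scheme)
    truth <- truth$labels
  }
  if (inherits(predicted, "label_map")) predicted <- predicted$labels
  if (!identical(dim(truth), dim(predicted)))
    stopf("truth and prediction shapes differ")
  if (is.null(n_classes)) n_classes <- max(truth, predicted)
  keep <- truth > 0
  t_v <- truth[keep]; p_v <- predicted[keep]
  if (length(t_v) == 0) stopf("no labeled pixels to score")
  if (any(p_v < 1 | p_v > n_classes))
    stopf("prediction contains class ids outside the scheme (1..%d)", n_classes)
  cm <- matrix(0L, n_classes, n_classes)
  tab <- table(factor(t_v, levels = seq_len(n_classes)),
               factor(p_v, levels = seq_len(n_classes)))
  cm[] <- as.integer(tab)
  nms <- if (!is.null(scheme)) scheme$classes else as.character(seq_len(n_classes))
  dimnames(cm) <- list(truth = nms, predicted = nms)
  cm
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, F1 their
#' harmonic mean; a zero denominator yields 0 with `undefined = TRUE`.
#' Macro averages run over classes present in the truth.
#'
#' @param confusion `C x C` counts (rows = truth).
#' @return A tibble with columns `class`, `truth_n`, `precision`, `recall`,
#'   `f1`, `undefined`, plus attributes `macro_precision`, `macro_recall`,
#'   `macro_f1`.
#' @export
precision_recall_f1 <- function(confusion) {
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  undef <- (tp + fp) == 0 | (tp + fn) == 0
  out <- tibble::tibble(
    class = rownames(confusion) %||% as.character(seq_along(tp)),
    truth_n = unname(rowSums(confusion)),
    precision = unname(prec), recall = unname(rec), f1 = unname(f1),
    undefined = unname(undef))
  present <- out$truth_n > 0
  attr(out, "macro_precision") <- mean(out$precision[present])
  attr(out, "macro_recall") <- mean(out$recall[present])
  attr(out, "macro_f1") <- mean(out$f1[present])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Overall accuracy
#'
#' Trace over total of the confusion matrix.
#'
#' @param confusion `C x C` counts.
#' @return Fraction in `[0, 1]`.
#' @export
overall_accuracy <- function(confusion) {
  tot <- sum(confusion)
  if (tot == 0) stopf("empty confusion matrix after masking")
  sum(diag(confusion)) / tot
}

#' Collapse a confusion matrix to first-level groups
#'
#' Rows and columns are summed within each first-level group of the scheme;
#' confusion between secondary classes of the same group becomes correct, so
#' collapsing never decreases overall accuracy.
#'
#' @param confusion `C x C` counts with classes ordered by id.
#' @param scheme a [class_scheme()] grouping every class.
#' @return `list(confusion = G x G counts, metrics = per-group tibble from
#'   [precision_recall_f1()], accuracy = grouped overall accuracy)`.
#' @export
group_metrics <- function(confusion, scheme) {
  stopifnot(inherits(scheme, "class_scheme"))
  if (nrow(confusion) != n_classes(scheme))
    stopf("confusion matrix does not match the scheme")
  groups <- unique(scheme$groups)
  A <- vapply(groups, function(g) as.numeric(scheme$groups == g),
              numeric(n_classes(scheme)))
  gcm <- t(A) %*% confusion %*% A
  dimnames(gcm) <- list(truth = groups, predicted = groups)
  list(confusion = gcm, metrics = precision_recall_f1(gcm),
       accuracy = overall_accuracy(gcm))
}

#' Full metrics report
#'
#' Bundles the confusion matrix, per-class precision/recall/F1, macro
#' averages, first-level group F1 and overall accuracy.
#'
#' @param truth a [label_map()] (its scheme provides names and groups).
#' @param predicted a [label_map()] or integer matrix.
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(truth, predicted) {
  stopifnot(inherits(truth, "label_map"))
  cm <- confusion_matrix(truth, predicted)
  pc <- precision_recall_f1(cm)
  grp <- group_metrics(cm, truth$scheme)
  structure(list(confusion = cm, per_class = pc,
                 macro_precision = attr(pc, "macro_precision"),
                 macro_recall = attr(pc, "macro_recall"),
                 macro_f1 = attr(pc, "macro_f1"),
                 grouped = grp,
                 overall_accuracy = overall_accuracy(cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> overall accuracy %.2f%%, macro P %.2f%% R %.2f%% F1 %.2f%%\n",
              100 * x$overall_accuracy, 100 * x$macro_precision,
              100 * x$macro_recall, 100 * x$macro_f1))
  g <- x$grouped$metrics
  cat("  group F1 (%):", paste(sprintf("%s %.2f", g$class, 100 * g$f1),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a metrics report
#'
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return Per-class tibble (the `per_class` table).
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of a metrics report
#'
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return One-row tibble: overall accuracy and macro averages.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(overall_accuracy = x$overall_accuracy,
                 macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall,
                 macro_f1 = x$macro_f1)
}

#' @export
glance <- function(x, ...) UseMethod("glance")
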