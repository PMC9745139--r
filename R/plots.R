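# ggplot2 visual summaries.

#' Plot training history
#'
#' Loss and pixel accuracy per epoch (validation curves included when the
#' fit tracked them).
#'
#' @param fit an `hsiseg_fit` (or its `history` tibble).
#' @return A ggplot object.
#' @export
plot_training_history <- function(fit) {
  h <- if (inherits(fit, "hsiseg_fit")) fit$history else fit
  long <- rbind(
    data.frame(epoch = h$epoch, value = h$loss, metric = "loss", role = "train"),
    data.frame(epoch = h$epoch, value = h$accuracy, metric = "accuracy", role = "train"))
  if (!all(is.na(h$val_loss)))
    long <- rbind(long,
      data.frame(epoch = h$epoch, value = h$val_loss, metric = "loss", role = "validation"),
      data.frame(epoch = h$epoch, value = h$val_accuracy, metric = "accuracy", role = "validation"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$role)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a label map
#'
#' Color-coded class raster (origin top-left).
#'
#' @param x a [label_map()].
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_label_map <- function(x, title = NULL) {
  stopifnot(inherits(x, "label_map"))
  lab <- x$labels
  df <- data.frame(row = rep(seq_len(nrow(lab)), ncol(lab)),
                   col = rep(seq_len(ncol(lab)), each = nrow(lab)),
                   class = factor(as.vector(lab), levels = 0:n_classes(x$scheme),
                                  labels = c("unlabeled", x$scheme$classes)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 .data
NULL

#' Plot an experiment comparison
#'
#' Overall held-out accuracy per variant, in run order.
#'
#' @param x an `hsiseg_experiment` from [run_experiment()].
#' @return A ggplot object.
#' @export
plot_experiment <- function(x) {
  stopifnot(inherits(x, "hsiseg_experiment"))
  t <- x$table
  t$variant <- factor(t$variant, levels = t$variant)
  ggplot2::ggplot(t, ggplot2::aes(x = .data$variant, y = .data$overall_accuracy)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = NULL, y = "overall accuracy",
                  title = sprintf("experiment %s", x$name)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
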