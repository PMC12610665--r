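#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an evaluation report
#'
#' One row per class with precision, recall, and F1, broom-style.
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble with columns `class`, `precision`, `recall`, `f1`.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(class = names(x$per_class_recall),
                 precision = unname(x$per_class_precision),
                 recall = unname(x$per_class_recall),
                 f1 = unname(x$per_class_f1))
}

#' One-row summary of an evaluation report
#'
#' @inheritParams tidy.eval_report
#' @return A one-row tibble: `accuracy`, `precision`, `recall`, `f1`,
#'   `kappa`, `auc_roc`, `ap`, `n` (and `fold` when set).
#' @export
glance.eval_report <- function(x, ...) {
  out <- tibble::tibble(accuracy = x$accuracy, precision = x$precision,
                        recall = x$recall, f1 = x$f1, kappa = x$kappa,
                        auc_roc = x$auc_roc %||% NA_real_,
                        ap = x$ap %||% NA_real_, n = x$n)
  if (!is.null(x$fold)) out <- cbind(tibble::tibble(fold = x$fold), out)
  tibble::as_tibble(out)
}

#' Tidy a confusion matrix into long format
#'
#' @param x A [confusion_matrix].
#' @param ... Unused.
#' @return Tibble with columns `actual`, `predicted`, `n`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  labels <- rownames(x)
  tibble::tibble(actual = rep(labels, times = length(labels)),
                 predicted = rep(labels, each = length(labels)),
                 n = as.integer(t(unclass(x))))
}

#' Plot a training history
#'
#' Loss and accuracy per epoch for train (and test, when recorded).
#'
#' @param object A `wcnn_history` tibble (`model$history`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wcnn_history <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- rbind(
    data.frame(epoch = df$epoch, metric = "loss", split = "train", value = df$train_loss),
    data.frame(epoch = df$epoch, metric = "accuracy", split = "train", value = df$train_accuracy),
    if (any(!is.na(df$test_loss)))
      data.frame(epoch = df$epoch, metric = "loss", split = "test", value = df$test_loss),
    if (any(!is.na(df$test_accuracy)))
      data.frame(epoch = df$epoch, metric = "accuracy", split = "test", value = df$test_accuracy)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a tile map
#'
#' @param object A [confusion_matrix].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy.confusion_matrix(object)
  labels <- rownames(object)
  df$actual <- factor(df$actual, rev(labels))
  df$predicted <- factor(df$predicted, labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "actual") +
    ggplot2::theme_minimal()
}

#' Plot a Grad-CAM heatmap over the MFCC plane
#'
#' @param object A `gradcam_heatmap` from [gradcam].
#' @param ... Unused.
#' @return A ggplot object with axes "frame" x "MFCC dimension".
#' @export
autoplot.gradcam_heatmap <- function(object, ...) {
  m <- unclass(object)
  df <- data.frame(dimension = rep(seq_len(nrow(m)), ncol(m)),
                   frame = rep(seq_len(ncol(m)), each = nrow(m)),
                   attention = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$dimension,
                                   fill = .data$attention)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "frame", y = "MFCC dimension",
                  title = paste("Grad-CAM:", attr(object, "target_class"))) +
    ggplot2::theme_minimal()
}

#' Plot a feature map
#'
#' @param object A `feature_map` from [extract_mfcc].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_map <- function(object, ...) {
  m <- unclass(object)
  df <- data.frame(dimension = rep(seq_len(nrow(m)), ncol(m)),
                   frame = rep(seq_len(ncol(m)), each = nrow(m)),
                   value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$dimension,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "frame", y = "MFCC dimension") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
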