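# broom-style tidiers and ggplot2 autoplot methods for the package's result
# objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.model_budget <- function(x, ...) x$layers

#' @export
glance.model_budget <- function(x, ...) {
  tibble::tibble(total_params = x$total_params,
                 stored_values = x$stored_values,
                 param_memory_mib = x$param_memory_mib,
                 head_pct = round(x$head_params / x$stored_values * 100, 2))
}

#' @export
tidy.mac_budget <- function(x, ...) x$layers

#' @export
glance.mac_budget <- function(x, ...) {
  tibble::tibble(total_macs = x$total_macs, macs_m = x$macs_m)
}

#' @export
tidy.ppw_fit <- function(x, ...) x$log

#' @export
glance.ppw_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(epochs = nrow(x$log), final_loss = last$loss,
                 final_acc = last$acc, final_val_acc = last$val_acc,
                 final_lr = last$lr)
}

#' @export
tidy.ppw_eval <- function(x, ...) x$per_class

#' @export
glance.ppw_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$overall_accuracy,
                 precision = x$macro$precision, recall = x$macro$recall,
                 f1 = x$macro$f1, auc = x$auc, n = x$n)
}

#' Training-curve plot
#' @param object a `ppw_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ppw_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$log, cols = c("loss", "acc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "training curves") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heat map
#' @param object a `ppw_confusion` matrix.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ppw_confusion <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame.table(unclass(object),
                                              responseName = "count"))
  names(df)[1:2] <- c("truth", "pred")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted", y = "true", title = "confusion matrix") +
    ggplot2::theme_minimal()
}
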