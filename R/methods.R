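# broom-style accessors and ggplot2 methods for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training loss trace of a classifier
#' @param x a [train_classifier()] model.
#' @param ... unused.
#' @return tibble with columns `epoch`, `loss`.
#' @export
tidy.gv_classifier <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' One-row summary of a classifier fit
#' @param x a [train_classifier()] model.
#' @param ... unused.
#' @export
glance.gv_classifier <- function(x, ...) {
  n_par <- sum(vapply(
    if (x$variant == "gsa") x$gsa[c("Wq", "Wk", "Wv", "Wo", "R")]
    else x$gcn,
    length, integer(1))) +
    sum(vapply(x$readout[c("W1", "b1", "W2", "b2")], length, integer(1)))
  tibble::tibble(
    variant = x$variant,
    epochs = length(x$loss_trace),
    final_loss = if (length(x$loss_trace)) utils::tail(x$loss_trace, 1)
    else NA_real_,
    n_parameters = n_par,
    seed = x$seed
  )
}

#' Tidy an evaluation report into long form
#' @param x a [evaluate_predictions()] report.
#' @param ... unused.
#' @export
tidy.gv_eval <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @export
glance.gv_eval <- function(x, ...) x$metrics

#' ROC curve plot
#' @param object a [roc_auc()] result.
#' @param ... unused.
#' @export
autoplot.gv_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    )
}

#' @export
autoplot.gv_eval <- function(object, ...) autoplot(object$roc, ...)

#' Training-loss plot
#' @param object a [train_classifier()] model.
#' @param ... unused.
#' @export
autoplot.gv_classifier <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Training loss",
                  title = sprintf("%s classifier training", object$variant))
}

#' Benchmark metric comparison plot
#' @param object a [run_benchmark()] result.
#' @param ... unused.
#' @export
autoplot.gv_benchmark <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, -"model",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                     fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Value", fill = "Model")
}
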