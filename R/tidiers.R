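# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training log of a language model
#'
#' @param x A `clm_model`.
#' @param ... Unused.
#' @return The step-indexed training log tibble (`step`, `epoch`, `lr`,
#'   `train_loss`, `val_loss`).
#' @method tidy clm_model
#' @export
tidy.clm_model <- function(x, ...) x$log

#' One-row summary of a language model fit
#'
#' @param x A `clm_model`.
#' @param ... Unused.
#' @return A tibble with parameter count, layer/width configuration, and
#'   final training/validation losses.
#' @method glance clm_model
#' @export
glance.clm_model <- function(x, ...) {
  tl <- x$log$train_loss[!is.na(x$log$train_loss)]
  vl <- x$log$val_loss[!is.na(x$log$val_loss)]
  tibble::tibble(
    n_parameters = sum(unlist(tree_map(length, x$params))),
    n_layers = x$config$n_layers, d_model = x$config$d_model,
    epochs = x$config$epochs,
    final_train_loss = if (length(tl)) utils::tail(tl, 1) else NA_real_,
    final_val_loss = if (length(vl)) utils::tail(vl, 1) else NA_real_
  )
}

#' Tidy the per-epoch history of a trained RCNN
#'
#' @param x An `rcnn_model` with history.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @method tidy rcnn_model
#' @export
tidy.rcnn_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history", call. = FALSE)
  x$history
}

#' One-row summary of a trained RCNN
#'
#' @param x An `rcnn_model`.
#' @param ... Unused.
#' @return A tibble with the final-epoch metrics on both sets.
#' @method glance rcnn_model
#' @export
glance.rcnn_model <- function(x, ...) {
  n_par <- sum(unlist(tree_map(length, x$params)))
  if (is.null(x$history)) {
    return(tibble::tibble(n_parameters = n_par, epochs = 0))
  }
  h <- x$history[nrow(x$history), ]
  tibble::tibble(n_parameters = n_par, epochs = h$epoch,
                 train_loss = h$train_loss, val_loss = h$val_loss,
                 train_r = h$train_r, val_r = h$val_r,
                 train_r2 = h$train_r2, val_r2 = h$val_r2,
                 train_rmse = h$train_rmse, val_rmse = h$val_rmse)
}

#' Tidy a repeated-experiment result
#'
#' @param x An `rcnn_repeat`.
#' @param ... Unused.
#' @return The per-repeat metric tibble.
#' @method tidy rcnn_repeat
#' @export
tidy.rcnn_repeat <- function(x, ...) x$runs

#' Mean/SD summary of a repeated experiment
#'
#' @param x An `rcnn_repeat`.
#' @param ... Unused.
#' @return The per-metric mean (SD) tibble.
#' @method glance rcnn_repeat
#' @export
glance.rcnn_repeat <- function(x, ...) x$summary

#' Plot language-model loss curves
#'
#' @param object A `clm_model`.
#' @param ... Unused.
#' @return A ggplot of training (and, where logged, validation) loss by
#'   optimizer step.
#' @method autoplot clm_model
#' @export
autoplot.clm_model <- function(object, ...) {
  log <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss"),
                             names_to = "set", values_to = "loss")
  log <- log[!is.na(log$loss), ]
  ggplot2::ggplot(log, ggplot2::aes(x = .data$step, y = .data$loss,
                                    colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = log[log$set == "val_loss", ]) +
    ggplot2::labs(x = "optimizer step", y = "cross-entropy loss",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot RCNN training history
#'
#' @param object An `rcnn_model` with history.
#' @param metric One of `"loss"`, `"rmse"`, `"r2"`, `"r"`.
#' @param ... Unused.
#' @return A ggplot of the chosen metric by epoch for both sets.
#' @method autoplot rcnn_model
#' @export
autoplot.rcnn_model <- function(object, metric = c("loss", "rmse", "r2", "r"),
                                ...) {
  metric <- match.arg(metric)
  if (is.null(object$history)) stop("model has no training history", call. = FALSE)
  cols <- paste0(c("train_", "val_"), metric)
  h <- tidyr::pivot_longer(object$history, dplyr::all_of(cols),
                           names_to = "set", values_to = "value")
  h <- h[!is.na(h$value), ]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = metric, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a generation quality report
#'
#' @param object A `generation_report`.
#' @param ... Unused.
#' @return A ggplot bar chart of the four quality metrics.
#' @method autoplot generation_report
#' @export
autoplot.generation_report <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object[, c("validity_nonempty", "uniqueness", "diversity", "mean_qed")],
    dplyr::everything(), names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "score") +
    ggplot2::theme_minimal()
}
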