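#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for fitted and summary objects
#'
#' `tidy()` returns the per-unit table (iterations, epochs, classes, folds);
#' `glance()` a one-row summary.
#'
#' @param x The object.
#' @param ... Unused.
#' @return A tibble.
#' @name amwnet-tidiers
NULL

#' @rdname amwnet-tidiers
#' @exportS3Method generics::tidy
tidy.tpsao_result <- function(x, ...) x$history

#' @rdname amwnet-tidiers
#' @exportS3Method generics::glance
glance.tpsao_result <- function(x, ...) {
  tibble::tibble(best_fitness = x$best_fitness,
                 iterations = nrow(x$history),
                 n_evals = x$n_evals)
}

#' @rdname amwnet-tidiers
#' @exportS3Method generics::tidy
tidy.lr_search_result <- function(x, ...) x$trace

#' @rdname amwnet-tidiers
#' @exportS3Method generics::glance
glance.lr_search_result <- function(x, ...) {
  tibble::tibble(best_lr = x$best_lr, best_fitness = x$best_fitness,
                 lower_bound = x$bounds[1], upper_bound = x$bounds[2])
}

#' @rdname amwnet-tidiers
#' @exportS3Method generics::tidy
tidy.amwnet_fit <- function(x, ...) x$history

#' @rdname amwnet-tidiers
#' @exportS3Method generics::glance
glance.amwnet_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history),
                 best_test_accuracy = x$best$accuracy,
                 final_train_loss = utils::tail(x$history$train_loss, 1),
                 n_parameters = n_parameters(x$model))
}

#' @rdname amwnet-tidiers
#' @exportS3Method generics::tidy
tidy.classification_report <- function(x, ...) x$per_class

#' @rdname amwnet-tidiers
#' @exportS3Method generics::glance
glance.classification_report <- function(x, ...) x$macro

#' @rdname amwnet-tidiers
#' @exportS3Method generics::tidy
tidy.kfold_result <- function(x, ...) x$folds

#' @rdname amwnet-tidiers
#' @exportS3Method generics::glance
glance.kfold_result <- function(x, ...) {
  tibble::tibble(k = nrow(x$folds), mean_accuracy = x$mean_accuracy,
                 sd_accuracy = stats::sd(x$folds$accuracy))
}

#' Plot methods
#'
#' Convergence curve for an optimizer run, training curves for a fit, and a
#' confusion-matrix heat map for a classification report.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name amwnet-autoplot
NULL

#' @rdname amwnet-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.tpsao_result <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "best fitness (log scale)",
                  title = "TPSAO convergence")
}

#' @rdname amwnet-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.lr_search_result <- function(object, ...) {
  autoplot.tpsao_result(object, ...) +
    ggplot2::labs(title = "Learning-rate search convergence")
}

#' @rdname amwnet-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.amwnet_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training curves")
}

#' @rdname amwnet-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.classification_report <- function(object, ...) {
  cm <- unclass(object$confusion)
  df <- tidyr::expand_grid(true = seq_len(nrow(cm)) - 1L,
                           predicted = seq_len(ncol(cm)) - 1L)
  df$count <- as.vector(t(cm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(title = "Confusion matrix (rows = true class)")
}

#' @importFrom rlang .data
NULL
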