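#' Plot a correlation matrix as a heatmap
#'
#' @param object A `correlation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_report <- function(object, ...) {
  feats <- object$features
  long <- tidyr::expand_grid(feature1 = feats, feature2 = feats) |>
    dplyr::mutate(r = object$r[cbind(.data$feature1, .data$feature2)],
                  feature1 = factor(.data$feature1, levels = feats),
                  feature2 = factor(.data$feature2, levels = rev(feats)))
  ggplot2::ggplot(long, ggplot2::aes(.data$feature1, .data$feature2,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a training trace
#'
#' @param object A `training_trace` (the `trace` element of an
#'   `mlp_model`).
#' @param ... Unused.
#' @return A ggplot of training MSE against epoch, with the convergence
#'   threshold drawn where the trace crosses it.
#' @export
autoplot.training_trace <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$mse), mse = object$mse)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$mse)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::labs(x = "Epoch", y = "Training MSE") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mlp_model <- function(object, ...) {
  autoplot(object$trace, ...) +
    ggplot2::geom_hline(yintercept = object$config$target_mse,
                        linetype = "dashed")
}

#' Plot the cross-method results grid
#'
#' @param object A `va_report`.
#' @param ... Unused.
#' @return A bar chart of test RMSE by method, faceted by emotion dimension
#'   and feature set; "no model" cells are omitted (they have no RMSE).
#' @export
autoplot.va_report <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !.data$no_model)
  ggplot2::ggplot(df, ggplot2::aes(.data$method, .data$rmse,
                                   fill = .data$feature_set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~dimension) +
    ggplot2::labs(x = NULL, y = "Test RMSE (0-1 scale)",
                  fill = "Features") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
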