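#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a committee model
#'
#' @param x A `committee_model`.
#' @param ... Unused.
#' @return One row per term (`perception`, `feeling`, `intercept`) with the
#'   estimate and, for the two ensemble terms, the contribution percentage.
#' @export
tidy.committee_model <- function(x, ...) {
  cc <- contributions(x)
  tibble::tibble(
    term = c("perception", "feeling", "intercept"),
    estimate = c(x$b_perc, x$b_feel, x$intercept),
    contribution_pct = c(cc$perc_pct, cc$feel_pct, NA_real_))
}

#' @rdname tidy.committee_model
#' @return `glance()`: a one-row model summary (dimension, n, in-sample
#'   r.squared and RMSE).
#' @export
glance.committee_model <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(dimension = x$dimension, n = x$n,
                 r.squared = s$r.squared,
                 rmse = sqrt(mean(stats::residuals(x$fit)^2)))
}

#' Tidy a trained network
#'
#' @param x An `mlp_model`.
#' @param ... Unused.
#' @return Long tibble of weights: layer, from-unit, to-unit, weight.
#' @export
tidy.mlp_model <- function(x, ...) {
  net <- x$net
  inputs <- x$features %||% paste0("in", seq_len(net$n_in))
  hidden <- paste0("h", seq_len(net$n_hidden))
  dplyr::bind_rows(
    tidyr::expand_grid(to = hidden, from = inputs) |>
      dplyr::mutate(layer = "input->hidden",
                    weight = as.vector(t(net$W_hi))),
    tibble::tibble(layer = "hidden->output", from = hidden, to = "out",
                   weight = as.vector(net$W_oh)),
    tibble::tibble(layer = "bias", from = c(hidden, "out"),
                   to = c(hidden, "out"),
                   weight = c(net$b_h, net$b_o))
  )[c("layer", "from", "to", "weight")]
}

#' @rdname tidy.mlp_model
#' @return `glance()`: one row with epochs run, convergence flag, final
#'   training MSE.
#' @export
glance.mlp_model <- function(x, ...) {
  tr <- x$trace
  tibble::tibble(epochs_run = tr$epochs_run, converged = tr$converged,
                 final_mse = tr$mse[length(tr$mse)],
                 n_in = x$net$n_in, n_hidden = x$net$n_hidden)
}

#' Tidy a stepwise model
#'
#' @param x A `stepwise_model`.
#' @param ... Unused.
#' @return Tibble of coefficients (empty for a "no model" outcome).
#' @export
tidy.stepwise_model <- function(x, ...) {
  if (x$no_model) {
    return(tibble::tibble(term = character(), estimate = double()))
  }
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' Tidy a feature-reduction result
#'
#' @param x A `feature_reduction`.
#' @param ... Unused.
#' @return The removal trace tibble.
#' @export
tidy.feature_reduction <- function(x, ...) x$trace

#' Tidy a correlation report
#'
#' @param x A `correlation_report`.
#' @param ... Unused.
#' @return Long tibble of unique feature pairs and their Pearson r.
#' @export
tidy.correlation_report <- function(x, ...) x$pairs
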