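#' Training configuration for the multilayer perceptron
#'
#' @param learning_rate Gradient-descent step size applied to the summed
#'   per-epoch weight changes.
#' @param target_mse Stopping threshold: training stops once the epoch's
#'   mean squared error (on the 0-1 target scale, over the training set)
#'   falls below this value.
#' @param max_epochs Upper bound on epochs; hitting it without reaching
#'   `target_mse` raises a warning and keeps the best weights seen.
#' @param init_half_range Weights initialize uniformly in
#'   `(-init_half_range, +init_half_range)`.
#' @param use_bias Include bias terms on hidden and output units. The
#'   network is also usable in a strict no-bias mode.
#' @param seed Seed controlling initialization and per-epoch presentation
#'   order.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 0.1, target_mse = 0.045,
                            max_epochs = 50000L, init_half_range = 0.05,
                            use_bias = TRUE, seed = 1L) {
  if (learning_rate < 0 || target_mse <= 0 || target_mse >= 1 ||
      max_epochs < 0 || init_half_range <= 0) {
    abort("Invalid training configuration.", class = "vacommittee_config_error")
  }
  structure(list(learning_rate = learning_rate, target_mse = target_mse,
                 max_epochs = as.integer(max_epochs),
                 init_half_range = init_half_range,
                 use_bias = isTRUE(use_bias), seed = as.integer(seed)),
            class = "training_config")
}

#' Initialize network weights
#'
#' A single-hidden-layer feedforward network: `W_hi` (hidden x input)
#' connects inputs to hidden units, `W_oh` (1 x hidden) connects hidden
#' units to the single output. All weights (and biases, when enabled) draw
#' uniformly from `(-init_half_range, +init_half_range)`.
#'
#' @param n_in Number of input units.
#' @param n_hidden Number of hidden units (default 3).
#' @param config A [training_config()]; its seed fixes the draw.
#' @return An `mlp_network` list of weight matrices.
#' @export
init_network <- function(n_in, n_hidden = 3L, config = training_config()) {
  stopifnot(n_in >= 1, n_hidden >= 1)
  set.seed(substream_seed(config$seed, "init"))
  r <- config$init_half_range
  net <- list(
    W_hi = matrix(runif(n_hidden * n_in, -r, r), n_hidden, n_in),
    W_oh = matrix(runif(n_hidden, -r, r), 1L, n_hidden),
    b_h = if (config$use_bias) runif(n_hidden, -r, r) else rep(0, n_hidden),
    b_o = if (config$use_bias) runif(1L, -r, r) else 0,
    use_bias = config$use_bias,
    n_in = as.integer(n_in),
    n_hidden = as.integer(n_hidden)
  )
  structure(net, class = "mlp_network")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass over a batch; returns hidden activations and outputs.
forward_pass <- function(net, X) {
  H <- sigmoid(X %*% t(net$W_hi) +
                 matrix(net$b_h, nrow(X), net$n_hidden, byrow = TRUE))
  y <- sigmoid(as.vector(H %*% t(net$W_oh)) + net$b_o)
  list(H = H, y = y)
}

#' Forward pass through the network
#'
#' Hidden activations are the sigmoid of the weighted input sums; the output
#' is the sigmoid of the weighted hidden sums, so it always lies strictly
#' in (0, 1).
#'
#' @param net An `mlp_network`.
#' @param x A numeric input vector of length `n_in`, or a matrix / data
#'   frame with `n_in` columns for a batch.
#' @return Numeric vector of outputs in (0, 1).
#' @export
#' @examples
#' net <- init_network(2, 2, training_config(seed = 1))
#' net$W_hi <- diag(2); net$W_oh <- matrix(c(1, 1), 1)
#' net$b_h <- c(0, 0); net$b_o <- 0
#' mlp_forward(net, c(0, 0))  # sigmoid(1) = 0.731...
mlp_forward <- function(net, x) {
  stopifnot(inherits(net, "mlp_network"))
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != net$n_in) {
    abort(sprintf("Input has %d columns but network expects %d.",
                  ncol(X), net$n_in),
          class = "vacommittee_input_error")
  }
  forward_pass(net, X)$y
}

# Exact gradient of the summed squared error L = sum_i (y_i - t_i)^2 with
# respect to every weight, computed over the whole batch at once.
network_gradients <- function(net, X, Y) {
  fp <- forward_pass(net, X)
  H <- fp$H
  y <- fp$y
  d_o <- 2 * (y - Y) * y * (1 - y)              # n
  g_Woh <- matrix(d_o, 1) %*% H                 # 1 x h
  g_bo <- sum(d_o)
  d_h <- (d_o %*% net$W_oh) * H * (1 - H)       # n x h (outer product rows)
  g_Whi <- t(d_h) %*% X                         # h x i
  g_bh <- colSums(d_h)
  list(W_hi = g_Whi, W_oh = g_Woh, b_h = g_bh, b_o = g_bo,
       mse = mean((y - Y)^2))
}

#' One epoch of batch backpropagation
#'
#' Presents all training examples (in a freshly randomized order), computes
#' per-example squared-error gradients by backpropagation, and applies a
#' single weight update with the sum of all stored weight changes at the end
#' of the epoch. The update is therefore invariant to presentation order up
#' to floating-point association.
#'
#' @param net An `mlp_network`.
#' @param X Matrix of training inputs (rows = examples), scaled to \[0, 1\].
#' @param Y Numeric vector of targets in \[0, 1\].
#' @param config A [training_config()].
#' @return List with the updated `net` and the epoch `mse` (computed from
#'   the forward passes of this epoch, before the weight update).
#' @export
backprop_epoch <- function(net, X, Y, config = training_config()) {
  stopifnot(inherits(net, "mlp_network"))
  X <- as.matrix(X)
  if (nrow(X) != length(Y)) {
    abort("`X` and `Y` must have matching lengths.",
          class = "vacommittee_input_error")
  }
  ord <- sample.int(nrow(X))
  g <- network_gradients(net, X[ord, , drop = FALSE], Y[ord])
  if (!all(is.finite(g$W_hi)) || !all(is.finite(g$W_oh)) ||
      !all(is.finite(g$b_h)) || !is.finite(g$b_o)) {
    abort("Non-finite gradient encountered during backpropagation.",
          class = "vacommittee_numeric_error")
  }
  lr <- config$learning_rate
  net$W_hi <- net$W_hi - lr * g$W_hi
  net$W_oh <- net$W_oh - lr * g$W_oh
  if (net$use_bias) {
    net$b_h <- net$b_h - lr * g$b_h
    net$b_o <- net$b_o - lr * g$b_o
  }
  list(net = net, mse = g$mse)
}

#' Train a network by epoch-batched gradient descent
#'
#' Repeats [backprop_epoch()] until the training mean squared error drops
#' below `config$target_mse` or `config$max_epochs` is reached. On
#' non-convergence a warning is raised and the weights from the best epoch
#' seen are retained.
#'
#' @param X Training inputs (matrix or data frame, rows = examples) scaled
#'   to \[0, 1\].
#' @param Y Targets in \[0, 1\] (a single emotion dimension; valence and
#'   arousal networks are always trained separately).
#' @param config A [training_config()].
#' @param n_hidden Hidden units (default 3).
#' @param net Optional pre-initialized `mlp_network` (e.g. for resuming).
#' @return An `mlp_model`: the trained `net`, the feature names, and a
#'   `trace` (`training_trace`: per-epoch MSE, `epochs_run`, `converged`).
#' @export
train_mlp <- function(X, Y, config = training_config(), n_hidden = 3L,
                      net = NULL) {
  X <- as.matrix(X)
  if (nrow(X) == 0) {
    abort("Empty training set.", class = "vacommittee_input_error")
  }
  if (nrow(X) != length(Y)) {
    abort("`X` and `Y` must have matching lengths.",
          class = "vacommittee_input_error")
  }
  if (is.null(net)) net <- init_network(ncol(X), n_hidden, config)
  set.seed(substream_seed(config$seed, "epochs"))

  mse_trace <- numeric(config$max_epochs)
  best_net <- net
  best_mse <- Inf
  epochs <- 0L
  converged <- FALSE
  while (epochs < config$max_epochs) {
    step <- backprop_epoch(net, X, Y, config)
    epochs <- epochs + 1L
    mse_trace[epochs] <- step$mse
    if (step$mse < best_mse) {
      best_mse <- step$mse
      best_net <- net # weights that produced this epoch's forward passes
    }
    net <- step$net
    if (step$mse < config$target_mse) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf(paste("Network did not reach target MSE %g in %d epochs",
                       "(best %0.4f); best-so-far weights retained."),
                 config$target_mse, config$max_epochs, best_mse))
    net <- best_net
  }
  trace <- structure(list(mse = mse_trace[seq_len(epochs)],
                          epochs_run = epochs, converged = converged),
                     class = "training_trace")
  structure(list(net = net, features = colnames(X), trace = trace,
                 config = config, n_hidden = net$n_hidden),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("<mlp_model> %d-%d-1 network; %d epochs, %s (final MSE %0.4f)\n",
              x$net$n_in, x$net$n_hidden, tr$epochs_run,
              if (tr$converged) "converged" else "not converged",
              tr$mse[length(tr$mse)]))
  invisible(x)
}

#' @export
predict.mlp_model <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) {
    as.matrix(newdata[object$features %||% colnames(newdata)])
  } else if (is.null(dim(newdata))) {
    matrix(newdata, nrow = 1)
  } else as.matrix(newdata)
  mlp_forward(object$net, X)
}

#' Root mean-squared error
#'
#' @param predictions,targets Numeric vectors of equal, positive length.
#' @return `sqrt(mean((predictions - targets)^2))`.
#' @export
rmse <- function(predictions, targets) {
  if (length(predictions) == 0 || length(predictions) != length(targets)) {
    abort("`predictions` and `targets` must be non-empty and equal length.",
          class = "vacommittee_input_error")
  }
  sqrt(mean((predictions - targets)^2))
}
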