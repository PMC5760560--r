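# Shared fixtures, built once per test run.

default_study <- simulate_study(generator_config(seed = 101))

tiny_config <- function(seed = 1) {
  generator_config(n_excerpts = 8L, genres = c("g1", "g2"),
                   excerpts_per_genre = 4L, n_participants = 8L,
                   excerpts_per_participant = 2L, raters_per_excerpt = 2L,
                   seed = seed)
}

# A constant-output network: zero hidden-to-output weights and an output
# bias at the logit of the wanted constant.
constant_net_model <- function(value, n_in = 2L) {
  net <- init_network(n_in, 2L, training_config(seed = 1))
  net$W_oh[] <- 0
  net$b_o <- stats::qlogis(value)
  structure(list(net = net, features = paste0("f", seq_len(n_in)),
                 trace = structure(list(mse = 0, epochs_run = 0L,
                                        converged = TRUE),
                                   class = "training_trace"),
                 config = training_config(seed = 1), n_hidden = 2L),
            class = "mlp_model")
}

no_model_stepwise <- function() {
  structure(list(selected = character(0), coefficients = NULL, fit = NULL,
                 no_model = TRUE, response = "y",
                 trace = tibble::tibble(step = integer(), action = character(),
                                        feature = character(), p = double())),
            class = "stepwise_model")
}

# Flatten network weights for finite-difference checks.
net_get_params <- function(net) {
  c(as.vector(net$W_hi), as.vector(net$W_oh), net$b_h, net$b_o)
}

net_set_params <- function(net, theta) {
  n1 <- length(net$W_hi)
  n2 <- length(net$W_oh)
  n3 <- length(net$b_h)
  net$W_hi[] <- theta[seq_len(n1)]
  net$W_oh[] <- theta[n1 + seq_len(n2)]
  net$b_h <- theta[n1 + n2 + seq_len(n3)]
  net$b_o <- theta[n1 + n2 + n3 + 1L]
  net
}

# Central finite differences of the summed squared error.
fd_gradient <- function(net, X, Y, eps = 1e-6) {
  loss <- function(theta) {
    y <- mlp_forward(net_set_params(net, theta), X)
    sum((y - Y)^2)
  }
  theta <- net_get_params(net)
  vapply(seq_along(theta), function(i) {
    up <- theta; up[i] <- up[i] + eps
    dn <- theta; dn[i] <- dn[i] - eps
    (loss(up) - loss(dn)) / (2 * eps)
  }, double(1))
}

analytic_gradient_flat <- function(net, X, Y) {
  g <- vacommittee:::network_gradients(net, X, Y)
  c(as.vector(g$W_hi), as.vector(g$W_oh), g$b_h, g$b_o)
}
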