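test_that("initialization gives the right shapes and the documented range", {
  net <- init_network(10, 3, training_config(seed = 1))
  expect_equal(dim(net$W_hi), c(3, 10))
  expect_equal(dim(net$W_oh), c(1, 3))
  expect_true(all(abs(net_get_params(net)) < 0.05))
  net5 <- init_network(5, 3, training_config(seed = 2))
  expect_equal(dim(net5$W_hi), c(3, 5))
  expect_identical(init_network(10, 3, training_config(seed = 9)),
                   init_network(10, 3, training_config(seed = 9)))
  expect_false(identical(init_network(10, 3, training_config(seed = 9)),
                         init_network(10, 3, training_config(seed = 10))))
})

test_that("forward pass follows the sigmoid chain exactly", {
  net <- init_network(2, 2, training_config(seed = 1))
  net$W_hi <- diag(2)
  net$W_oh <- matrix(c(1, 1), 1)
  net$b_h <- c(0, 0)
  net$b_o <- 0
  # x = (0,0): hidden = sigmoid(0) = 0.5 twice; output = sigmoid(1)
  expect_equal(mlp_forward(net, c(0, 0)), 1 / (1 + exp(-1)), tolerance = 1e-12)
  net$W_oh[] <- 0
  expect_equal(mlp_forward(net, c(0.3, -0.2)), 0.5, tolerance = 1e-12)
})

test_that("outputs lie strictly inside (0, 1) for extreme inputs and weights", {
  net <- init_network(4, 3, training_config(seed = 2))
  net$W_hi[] <- rnorm(12, sd = 5)
  net$W_oh[] <- rnorm(3, sd = 5)
  X <- matrix(rnorm(40, sd = 3), 10, 4)
  y <- mlp_forward(net, X)
  expect_true(all(y > 0 & y < 1))
  expect_error(mlp_forward(net, c(1, 2)), class = "vacommittee_input_error")
})

test_that("analytic gradients match central finite differences", {
  set.seed(31)
  for (i in 1:25) {
    n_in <- sample(2:5, 1)
    n_h <- sample(1:3, 1)
    net <- init_network(n_in, n_h, training_config(seed = i))
    theta <- runif(length(net_get_params(net)), -1, 1)
    net <- net_set_params(net, theta)
    X <- matrix(runif(6 * n_in), 6, n_in)
    Y <- runif(6)
    a <- analytic_gradient_flat(net, X, Y)
    f <- fd_gradient(net, X, Y)
    rel <- abs(a - f) / pmax(abs(a), abs(f), 1e-6)
    expect_lt(max(rel), 1e-5)
  }
})

test_that("a zero learning rate leaves weights and loss untouched", {
  net <- init_network(3, 2, training_config(seed = 4))
  X <- matrix(runif(15), 5, 3)
  Y <- runif(5)
  cfg <- training_config(learning_rate = 0, seed = 4)
  step <- backprop_epoch(net, X, Y, cfg)
  expect_identical(step$net$W_hi, net$W_hi)
  expect_identical(step$net$W_oh, net$W_oh)
  expect_equal(backprop_epoch(net, X, Y, cfg)$mse, step$mse)
})

test_that("the batch update does not depend on presentation order", {
  net <- init_network(4, 3, training_config(seed = 5))
  X <- matrix(runif(40), 10, 4)
  Y <- runif(10)
  cfg <- training_config(seed = 5)
  set.seed(1)
  a <- backprop_epoch(net, X, Y, cfg)
  set.seed(99) # different presentation order
  b <- backprop_epoch(net, X, Y, cfg)
  expect_equal(a$net$W_hi, b$net$W_hi, tolerance = 1e-10)
  expect_equal(a$net$W_oh, b$net$W_oh, tolerance = 1e-10)
  expect_equal(a$mse, b$mse, tolerance = 1e-12)
})

test_that("training reaches the stopping threshold on a learnable target", {
  set.seed(8)
  X <- matrix(runif(80), 20, 4)
  Y <- 0.2 + 0.5 * X[, 1] # noise-free, within (0,1)
  model <- train_mlp(X, Y, training_config(seed = 8, max_epochs = 20000))
  expect_true(model$trace$converged)
  expect_lt(model$trace$mse[model$trace$epochs_run], 0.045)
  expect_lte(model$trace$mse[model$trace$epochs_run], model$trace$mse[1])
})

test_that("a zero-epoch budget returns the initial weights, unconverged", {
  X <- matrix(runif(12), 4, 3)
  Y <- runif(4)
  cfg <- training_config(seed = 3, max_epochs = 0)
  net0 <- init_network(3, 3, cfg)
  expect_warning(model <- train_mlp(X, Y, cfg, net = net0), "did not reach")
  expect_false(model$trace$converged)
  expect_equal(model$trace$epochs_run, 0L)
  expect_identical(model$net$W_hi, net0$W_hi)
})

test_that("training is deterministic in the seed", {
  X <- matrix(runif(60), 15, 4)
  Y <- runif(15)
  m1 <- suppressWarnings(train_mlp(X, Y, training_config(seed = 6, max_epochs = 200)))
  m2 <- suppressWarnings(train_mlp(X, Y, training_config(seed = 6, max_epochs = 200)))
  expect_identical(m1$net, m2$net)
  expect_identical(m1$trace$mse, m2$trace$mse)
})

test_that("rmse matches its definition and scales linearly", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 1), c(1, 1)), sqrt(0.5))
  p <- runif(10)
  t <- runif(10)
  expect_equal(rmse(3 * p, 3 * t), 3 * rmse(p, t), tolerance = 1e-12)
  expect_error(rmse(numeric(0), numeric(0)), class = "vacommittee_input_error")
  expect_error(rmse(1:3, 1:2), class = "vacommittee_input_error")
})
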