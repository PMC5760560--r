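test_that("stepwise forward picks the dominant predictor first", {
  set.seed(41)
  d <- tibble::as_tibble(matrix(rnorm(360), 36, 10,
                                dimnames = list(NULL, paste0("x", 1:10))))
  d$y <- 2 * d$x3 + rnorm(36, sd = 0.05)
  m <- stepwise_forward(d, "y", paste0("x", 1:10))
  expect_false(m$no_model)
  expect_equal(m$selected[1], "x3")
  # brute-force oracle: x3 has the smallest single-predictor p value
  ps <- vapply(paste0("x", 1:10), function(v) {
    summary(lm(stats::reformulate(v, "y"), data = d))$coefficients[2, 4]
  }, double(1))
  expect_equal(names(which.min(ps)), "x3")
})

test_that("no candidate meeting the entry criterion yields a no-model outcome", {
  set.seed(43)
  d <- tibble::as_tibble(matrix(rnorm(150), 30, 5,
                                dimnames = list(NULL, paste0("x", 1:5))))
  d$y <- rnorm(30)
  # confirm the fixture: every marginal p exceeds the entry threshold
  ps <- vapply(paste0("x", 1:5), function(v) {
    summary(lm(stats::reformulate(v, "y"), data = d))$coefficients[2, 4]
  }, double(1))
  expect_true(all(ps > 0.05))
  m <- stepwise_forward(d, "y", paste0("x", 1:5))
  expect_true(m$no_model)
  expect_true(is_no_model(m))
  expect_length(m$selected, 0)
})

test_that("single-predictor entry F equals the squared t statistic", {
  set.seed(44)
  d <- tibble::tibble(x = rnorm(25), y = rnorm(25))
  null_fit <- lm(y ~ 1, data = d)
  a1 <- add1(null_fit, scope = ~x, test = "F")
  t_stat <- summary(lm(y ~ x, data = d))$coefficients["x", "t value"]
  expect_equal(a1["x", "F value"], t_stat^2, tolerance = 1e-10)
})

test_that("entry and removal thresholds must not cycle", {
  d <- tibble::tibble(x = rnorm(20), y = rnorm(20))
  expect_error(stepwise_forward(d, "y", "x", p_enter = 0.1, p_remove = 0.1),
               class = "vacommittee_config_error")
})

test_that("stepwise ensembles average the members that produced a model", {
  d1 <- tibble::tibble(x = seq(0, 1, length.out = 20))
  d1$y <- d1$x # exact, so predictions are known in closed form
  m1 <- suppressWarnings(stepwise_forward(d1, "y", "x"))
  d2 <- d1
  d2$y <- 2 * d2$x
  m2 <- suppressWarnings(stepwise_forward(d2, "y", "x"))
  newdata <- tibble::tibble(x = c(0.2, 0.5))
  expect_equal(stepwise_ensemble_predict(list(m1), newdata),
               c(0.2, 0.5), tolerance = 1e-8, ignore_attr = TRUE)
  pred <- stepwise_ensemble_predict(list(m1, m2), newdata)
  expect_equal(pred, c(0.3, 0.75), tolerance = 1e-8, ignore_attr = TRUE)
  # no-model members are excluded and counted
  mixed <- list(m1, no_model_stepwise(), no_model_stepwise(),
                no_model_stepwise(), m2)
  pred2 <- stepwise_ensemble_predict(mixed, newdata)
  expect_equal(attr(pred2, "n_models"), 2L)
  expect_equal(as.numeric(pred2), c(0.3, 0.75), tolerance = 1e-8)
  # all no-model propagates
  none <- stepwise_ensemble_predict(list(no_model_stepwise()), newdata)
  expect_true(is_no_model(none))
  expect_true(all(is.na(none)))
})

test_that("forest predictions stay within the training response range", {
  set.seed(51)
  X <- tibble::as_tibble(matrix(runif(44 * 5), 44, 5,
                                dimnames = list(NULL, paste0("f", 1:5))))
  y <- runif(44, 0.2, 0.8)
  model <- fit_forest(X, y, forest_config(n_trees = 100, seed = 1))
  newX <- tibble::as_tibble(matrix(runif(50, -1, 2), 10, 5,
                                   dimnames = list(NULL, paste0("f", 1:5))))
  pred <- forest_predict(model, newX)
  expect_true(all(pred >= min(y) & pred <= max(y)))
})

test_that("forests learn a noise-free monotone signal far better than the mean", {
  set.seed(52)
  X <- tibble::tibble(x1 = runif(60), x2 = runif(60))
  y <- X$x1^2
  train <- seq_len(44)
  model <- fit_forest(X[train, ], y[train], forest_config(seed = 2))
  pred <- forest_predict(model, X[-train, ])
  rmse_forest <- rmse(pred, y[-train])
  rmse_mean <- rmse(rep(mean(y[train]), 16), y[-train])
  expect_lt(rmse_forest, 0.5 * rmse_mean)
})

test_that("forests are bit-reproducible at a fixed seed", {
  set.seed(53)
  X <- tibble::as_tibble(matrix(runif(120), 30, 4,
                                dimnames = list(NULL, paste0("f", 1:4))))
  y <- runif(30)
  cfg <- forest_config(n_trees = 50, seed = 7)
  p1 <- forest_predict(fit_forest(X, y, cfg), X)
  p2 <- forest_predict(fit_forest(X, y, cfg), X)
  expect_identical(p1, p2)
})

test_that("the results grid carries every arm and renders no-model cells", {
  arms <- tidyr::expand_grid(
    method = c("neural network", "stepwise regression", "random forest"),
    dimension = c("valence", "arousal"),
    feature_set = c("audio", "physio")) |>
    dplyr::mutate(rmse = runif(12, 0.1, 0.4), n_models = 5L,
                  no_model = FALSE, test_ids = list(letters[1:16]))
  arms$rmse[arms$method == "stepwise regression" &
              arms$dimension == "arousal" &
              arms$feature_set == "physio"] <- NA
  arms$no_model[arms$method == "stepwise regression" &
                  arms$dimension == "arousal" &
                  arms$feature_set == "physio"] <- TRUE
  committee <- tibble::tibble(method = c("CMEA", "CMLR"),
                              dimension = "valence",
                              rmse = c(0.28, 0.26))
  rep <- build_report(arms, committee)
  expect_s3_class(rep, "va_report")
  expect_equal(nrow(rep), 14)
  fr <- format_report(rep)
  expect_true("no model" %in% fr$display)
  expect_false(any(fr$rmse[!fr$no_model] < 0, na.rm = TRUE))
  # inconsistent test sets refuse to aggregate
  arms2 <- arms
  arms2$test_ids[[1]] <- letters[2:17]
  expect_error(build_report(arms2, committee),
               class = "vacommittee_input_error")
})

test_that("fold summaries aggregate mean and standard error", {
  s <- summarize_folds(c(0.27, 0.21, 0.16, 0.26, 0.16))
  expect_equal(s$mean, mean(c(0.27, 0.21, 0.16, 0.26, 0.16)))
  expect_equal(s$se, sd(c(0.27, 0.21, 0.16, 0.26, 0.16)) / sqrt(5))
})
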