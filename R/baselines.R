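#' Stepwise forward regression with entry/removal F tests
#'
#' Iteratively adds the candidate predictor whose partial F-test p value is
#' smallest and at most `p_enter`; after each addition, removes any included
#' predictor whose partial F-test p value has risen to `p_remove` or above.
#' Stops when no candidate enters. If nothing ever enters, the result is a
#' "no model" outcome, mirroring the situation where no feature satisfies
#' the inclusion criterion.
#'
#' @param data Data frame holding the response and candidate columns.
#' @param response Name of the response column.
#' @param candidates Character vector of candidate predictor columns.
#' @param p_enter Largest entry p value (probability of F to enter).
#' @param p_remove Smallest removal p value; must exceed `p_enter` to avoid
#'   entry/removal cycling.
#' @return A `stepwise_model`: `selected` (in entry order), `coefficients`,
#'   the `lm` `fit` (or `NULL`), logical `no_model`, and a `trace` tibble of
#'   entry/removal events.
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(30), x2 = rnorm(30), x3 = rnorm(30))
#' d$y <- 2 * d$x3 + rnorm(30, sd = 0.01)
#' stepwise_forward(d, "y", c("x1", "x2", "x3"))$selected
stepwise_forward <- function(data, response, candidates,
                             p_enter = 0.05, p_remove = 0.10) {
  if (p_enter >= p_remove) {
    abort("`p_enter` must be strictly smaller than `p_remove` (cycling hazard).",
          class = "vacommittee_config_error")
  }
  data <- as.data.frame(data)[c(response, candidates)]
  if (anyNA(data)) {
    abort("Stepwise regression requires complete data.",
          class = "vacommittee_input_error")
  }
  n <- nrow(data)
  selected <- character(0)
  trace <- list()
  step <- 0L
  fit <- lm(stats::reformulate("1", response), data = data)
  repeat {
    pool <- setdiff(candidates, selected)
    # entry requires residual df >= 2 after adding one more term
    if (length(pool) == 0 || n - (length(selected) + 2L) < 2L) break
    a1 <- add1(fit, scope = stats::reformulate(c(selected, pool)), test = "F")
    pvals <- setNames(a1[["Pr(>F)"]], rownames(a1))[pool]
    best <- names(which.min(pvals))
    if (length(best) == 0 || is.na(pvals[best]) || pvals[best] > p_enter) break
    selected <- c(selected, best)
    step <- step + 1L
    trace[[step]] <- tibble::tibble(step = step, action = "enter",
                                    feature = best, p = unname(pvals[best]))
    fit <- lm(stats::reformulate(selected, response), data = data)
    # backward pass: drop any included term whose p has risen to p_remove
    repeat {
      d1 <- drop1(fit, test = "F")
      dp <- setNames(d1[["Pr(>F)"]], rownames(d1))[selected]
      worst <- names(which.max(dp))
      if (length(worst) == 0 || is.na(dp[worst]) || dp[worst] < p_remove) break
      selected <- setdiff(selected, worst)
      step <- step + 1L
      trace[[step]] <- tibble::tibble(step = step, action = "remove",
                                      feature = worst, p = unname(dp[worst]))
      fit <- lm(stats::reformulate(if (length(selected)) selected else "1",
                                   response), data = data)
    }
  }
  no_model <- length(selected) == 0
  structure(list(selected = selected,
                 coefficients = if (no_model) NULL else coef(fit),
                 fit = if (no_model) NULL else fit,
                 no_model = no_model,
                 response = response,
                 trace = if (length(trace)) dplyr::bind_rows(trace)
                         else tibble::tibble(step = integer(), action = character(),
                                             feature = character(), p = double())),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  if (x$no_model) {
    cat("<stepwise_model> no model (no predictor met the entry criterion)\n")
  } else {
    cat("<stepwise_model>", x$response, "~",
        paste(x$selected, collapse = " + "), "\n")
  }
  invisible(x)
}

#' Is a stepwise result a "no model" outcome?
#' @param x A `stepwise_model` or a prediction vector.
#' @return Logical.
#' @export
is_no_model <- function(x) {
  if (inherits(x, "stepwise_model")) return(isTRUE(x$no_model))
  isTRUE(attr(x, "no_model"))
}

#' @export
predict.stepwise_model <- function(object, newdata, ...) {
  if (object$no_model) {
    out <- rep(NA_real_, nrow(as.data.frame(newdata)))
    attr(out, "no_model") <- TRUE
    return(out)
  }
  unname(predict(object$fit, newdata = as.data.frame(newdata)))
}

#' Ensemble prediction from per-fold stepwise models
#'
#' Averages predictions over the members that produced a model; folds with
#' a "no model" outcome are excluded. If every member is "no model", the
#' outcome propagates (an all-`NA` vector flagged with `no_model`).
#'
#' @param models List of `stepwise_model` objects.
#' @param newdata Data frame of predictors.
#' @return Numeric vector of averaged predictions, with attribute
#'   `n_models` (contributing folds); or a `no_model`-flagged NA vector.
#' @export
stepwise_ensemble_predict <- function(models, newdata) {
  stopifnot(all(vapply(models, inherits, logical(1), "stepwise_model")))
  active <- Filter(function(m) !m$no_model, models)
  if (length(active) == 0) {
    out <- rep(NA_real_, nrow(as.data.frame(newdata)))
    attr(out, "no_model") <- TRUE
    attr(out, "n_models") <- 0L
    return(out)
  }
  preds <- vapply(active, predict, double(nrow(as.data.frame(newdata))),
                  newdata = newdata)
  out <- if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
  attr(out, "n_models") <- length(active)
  out
}

#' Random-forest configuration
#'
#' @param n_trees Number of trees.
#' @param features_per_split Features tried at each split; default
#'   `max(1, floor(p / 3))`, the regression-forest convention.
#' @param min_leaf_size Minimum terminal-node size.
#' @param seed Seed for bootstrap and split randomness.
#' @return A `forest_config` list.
#' @export
forest_config <- function(n_trees = 500L, features_per_split = NULL,
                          min_leaf_size = 5L, seed = 1L) {
  if (n_trees < 1 || min_leaf_size < 1) {
    abort("Invalid forest configuration.", class = "vacommittee_config_error")
  }
  structure(list(n_trees = as.integer(n_trees),
                 features_per_split = features_per_split,
                 min_leaf_size = as.integer(min_leaf_size),
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Fit a bagged random-forest regressor
#'
#' Trees are grown on bootstrap resamples of the training data with random
#' feature subsets at each split; the forest prediction is the mean of the
#' tree predictions. Trained once on the full training split (no
#' cross-validation), as bagging already controls overfitting.
#'
#' @param X Data frame or matrix of predictors.
#' @param y Numeric response.
#' @param config A [forest_config()].
#' @return A `va_forest` wrapping the fitted forest.
#' @export
fit_forest <- function(X, y, config = forest_config()) {
  X <- as.data.frame(X)
  if (nrow(X) < 2) {
    abort("Random forest needs at least 2 training rows.",
          class = "vacommittee_input_error")
  }
  if (nrow(X) != length(y)) {
    abort("`X` and `y` must have matching lengths.",
          class = "vacommittee_input_error")
  }
  mtry <- config$features_per_split %||% max(1L, floor(ncol(X) / 3))
  set.seed(substream_seed(config$seed, "forest"))
  rf <- randomForest::randomForest(
    x = X, y = y, ntree = config$n_trees, mtry = mtry,
    nodesize = config$min_leaf_size, replace = TRUE)
  structure(list(rf = rf, features = names(X), config = config),
            class = "va_forest")
}

#' @rdname fit_forest
#' @param model A `va_forest`.
#' @param newdata Data frame of predictors.
#' @return `forest_predict()`: numeric predictions, each within the range
#'   of the training response.
#' @export
forest_predict <- function(model, newdata) {
  stopifnot(inherits(model, "va_forest"))
  unname(predict(model$rf, newdata = as.data.frame(newdata)[model$features]))
}

#' @export
predict.va_forest <- function(object, newdata, ...) {
  forest_predict(object, newdata)
}
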