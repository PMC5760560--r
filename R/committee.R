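#' Ensemble of fold-trained networks
#'
#' Bundles the five per-fold networks for one (dimension, feature set);
#' the ensemble prediction is the unweighted mean of the member outputs.
#'
#' @param models List of `mlp_model` objects sharing an input schema.
#' @param dimension `"valence"` or `"arousal"`.
#' @param feature_set Label, e.g. `"audio"` or `"physio"`.
#' @return An `mlp_ensemble`.
#' @export
mlp_ensemble <- function(models, dimension = NA_character_,
                         feature_set = NA_character_) {
  if (length(models) == 0) {
    abort("An ensemble needs at least one member network.",
          class = "vacommittee_input_error")
  }
  stopifnot(all(vapply(models, inherits, logical(1), "mlp_model")))
  feats <- lapply(models, function(m) m$features)
  if (length(unique(feats)) != 1) {
    abort("All ensemble members must share the same input features.",
          class = "vacommittee_input_error")
  }
  structure(list(models = models, dimension = dimension,
                 feature_set = feature_set, features = feats[[1]]),
            class = "mlp_ensemble")
}

#' Ensemble prediction: mean of member outputs
#'
#' @param ensemble An [mlp_ensemble()].
#' @param newdata Data frame or matrix of scaled inputs.
#' @return Numeric vector in (0, 1).
#' @export
ensemble_predict <- function(ensemble, newdata) {
  stopifnot(inherits(ensemble, "mlp_ensemble"))
  preds <- vapply(ensemble$models, predict,
                  double(if (is.null(dim(newdata))) 1L else nrow(newdata)),
                  newdata = newdata)
  if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
}

#' @export
predict.mlp_ensemble <- function(object, newdata, ...) {
  ensemble_predict(object, newdata)
}

#' Equal-weight committee machine (CMEA)
#'
#' Combines the perception-ensemble and feeling-ensemble outputs with equal
#' weight contributions of 0.5 each.
#'
#' @param p_out,f_out Perception and feeling ensemble outputs (numeric).
#' @return `0.5 * p_out + 0.5 * f_out`.
#' @export
cmea_predict <- function(p_out, f_out) {
  stopifnot(all(is.finite(p_out)), all(is.finite(f_out)))
  0.5 * p_out + 0.5 * f_out
}

#' Linear-regression committee machine (CMLR)
#'
#' Fits ordinary least squares of the mean ratings (0-1 scale) on the
#' perception-ensemble output and the feeling-ensemble output, giving the
#' stacking weights of the meta-level model
#' `y = b_perc * x1 + b_feel * x2 + intercept`.
#'
#' @param p_outs,f_outs Per-excerpt ensemble outputs.
#' @param targets Mean ratings on the 0-1 scale.
#' @param dimension Label stored with the model.
#' @return A `committee_model` with coefficients, the underlying `lm` fit,
#'   and the fitting-set size.
#' @export
fit_cmlr <- function(p_outs, f_outs, targets, dimension = NA_character_) {
  n <- length(targets)
  if (length(p_outs) != n || length(f_outs) != n) {
    abort("Ensemble outputs and targets must have equal length.",
          class = "vacommittee_input_error")
  }
  if (n < 3) {
    abort("Need at least 3 excerpts to fit the committee regression.",
          class = "vacommittee_input_error")
  }
  if (sd(p_outs) == 0 || sd(f_outs) == 0 ||
      abs(cor(p_outs, f_outs)) > 1 - 1e-12) {
    abort(paste("Committee predictors are collinear:",
                "perception and feeling ensemble outputs do not span a plane."),
          class = "vacommittee_numeric_error")
  }
  dat <- data.frame(y = targets, p = p_outs, f = f_outs)
  fit <- lm(y ~ p + f, data = dat)
  cf <- coef(fit)
  structure(list(b_perc = unname(cf["p"]), b_feel = unname(cf["f"]),
                 intercept = unname(cf["(Intercept)"]),
                 dimension = dimension, fit = fit, n = n),
            class = "committee_model")
}

#' CMLR prediction
#'
#' @param model A `committee_model` (or any list with `b_perc`, `b_feel`,
#'   `intercept`).
#' @param p_out,f_out Ensemble outputs.
#' @return `b_perc * p_out + b_feel * f_out + intercept`.
#' @export
cmlr_predict <- function(model, p_out, f_out) {
  stopifnot(all(is.finite(p_out)), all(is.finite(f_out)))
  model$b_perc * p_out + model$b_feel * f_out + model$intercept
}

#' Contribution percentages of the committee members
#'
#' The proportion contribution of each ensemble, ignoring the intercept:
#' `100 * |b_perc| / (|b_perc| + |b_feel|)` for the perception side and the
#' complement for the feeling side. Coefficient magnitudes are used so the
#' split is scale-invariant and robust to sign flips.
#'
#' @param model A `committee_model`, or a numeric length-2 vector
#'   `c(b_perc, b_feel)` of stacking coefficients.
#' @return A `contribution_report` tibble with columns `dimension`,
#'   `perc_pct`, `feel_pct` (percentages summing to 100, unrounded).
#' @export
#' @examples
#' contributions(c(0.757, 0.164))  # ~82.2 / 17.8
contributions <- function(model) {
  if (inherits(model, "committee_model")) {
    b <- c(model$b_perc, model$b_feel)
    dimension <- model$dimension
  } else if (is.numeric(model) && length(model) == 2) {
    b <- as.numeric(model)
    dimension <- NA_character_
  } else {
    abort("`model` must be a committee_model or a numeric pair of coefficients.",
          class = "vacommittee_input_error")
  }
  denom <- sum(abs(b))
  if (denom == 0) {
    abort("Both committee coefficients are zero; contributions undefined.",
          class = "vacommittee_numeric_error")
  }
  out <- tibble::tibble(dimension = dimension,
                        perc_pct = 100 * abs(b[1]) / denom,
                        feel_pct = 100 * abs(b[2]) / denom)
  structure(out, class = c("contribution_report", class(out)))
}

#' @export
print.committee_model <- function(x, ...) {
  cc <- contributions(x)
  cat(sprintf("<committee_model> %s: y = %.3f*x_perc + %.3f*x_feel + %.3f (n = %d)\n",
              x$dimension %||% "?", x$b_perc, x$b_feel, x$intercept, x$n))
  cat(sprintf("  contributions: perception %.1f%% | feeling %.1f%%\n",
              round_half_up(cc$perc_pct, 1), round_half_up(cc$feel_pct, 1)))
  invisible(x)
}
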