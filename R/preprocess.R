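#' Pearson correlation matrix of a feature table
#'
#' @param table Data frame of per-excerpt feature values.
#' @param features Character vector of columns to use; defaults to all
#'   numeric columns.
#' @return A `correlation_report`: the correlation matrix `r`, a long tibble
#'   `pairs` (`feature1`, `feature2`, `r`), the sample size `n`, and
#'   `zero_variance`, the names of constant columns (their correlations are
#'   undefined and reported as `NA`, treated as non-violations downstream).
#' @export
correlation_matrix <- function(table, features = NULL) {
  table <- tibble::as_tibble(table)
  if (is.null(features)) {
    features <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  missing <- setdiff(features, names(table))
  if (length(missing) > 0) {
    abort(paste0("Unknown features: ", paste(missing, collapse = ", ")),
          class = "vacommittee_input_error")
  }
  x <- as.matrix(table[features])
  if (nrow(x) < 3) {
    abort("Need at least 3 rows to compute correlations.",
          class = "vacommittee_input_error")
  }
  if (anyNA(x)) {
    abort("Feature table contains missing values.",
          class = "vacommittee_input_error")
  }
  sds <- apply(x, 2, sd)
  zero_var <- features[sds == 0]
  r <- suppressWarnings(cor(x))
  diag(r) <- 1
  pairs <- expand.grid(feature1 = features, feature2 = features,
                       stringsAsFactors = FALSE) |>
    tibble::as_tibble() |>
    dplyr::filter(.data$feature1 < .data$feature2) |>
    dplyr::mutate(r = r[cbind(.data$feature1, .data$feature2)])
  structure(list(r = r, pairs = pairs, n = nrow(x), features = features,
                 zero_variance = zero_var),
            class = "correlation_report")
}

#' Construct a correlation report from a known matrix
#'
#' Useful for driving [reduce_features()] from a published correlation
#' pattern rather than raw data.
#'
#' @param r Square symmetric correlation matrix with dimnames.
#' @param n Nominal sample size behind the matrix.
#' @return A `correlation_report`.
#' @export
as_correlation_report <- function(r, n = NA_integer_) {
  stopifnot(is.matrix(r), nrow(r) == ncol(r), !is.null(rownames(r)))
  if (max(abs(r - t(r)), na.rm = TRUE) > 1e-8) {
    abort("Correlation matrix must be symmetric.",
          class = "vacommittee_input_error")
  }
  features <- rownames(r)
  pairs <- expand.grid(feature1 = features, feature2 = features,
                       stringsAsFactors = FALSE) |>
    tibble::as_tibble() |>
    dplyr::filter(.data$feature1 < .data$feature2) |>
    dplyr::mutate(r = r[cbind(.data$feature1, .data$feature2)])
  structure(list(r = r, pairs = pairs, n = n, features = features,
                 zero_variance = character(0)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> %d features, n = %s\n",
              length(x$features), format(x$n)))
  print(round(x$r, 2))
  invisible(x)
}

#' Greedy correlation-threshold feature reduction
#'
#' While any pair of surviving features has `|r|` strictly above the
#' threshold, removes the feature with the most violating partners,
#' breaking ties first by the larger mean `|r|` to the remaining features,
#' then by input order. Undefined correlations (constant columns) never
#' count as violations.
#'
#' @param report A `correlation_report`.
#' @param threshold Absolute correlation above which a pair violates;
#'   default 0.8 (strict inequality).
#' @return A `feature_reduction`: `retained`, `removed` (in removal order),
#'   `trace` (tibble with one row per removal: step, feature, number of
#'   violating partners, mean `|r|` to then-remaining features), and the
#'   threshold.
#' @export
#' @examples
#' rep <- example_audio_correlations()
#' reduce_features(rep)$removed
reduce_features <- function(report, threshold = 0.8) {
  stopifnot(inherits(report, "correlation_report"))
  r <- abs(report$r)
  diag(r) <- NA
  features <- report$features
  keep <- features
  trace <- list()
  step <- 0L
  repeat {
    sub <- r[keep, keep, drop = FALSE]
    viol <- rowSums(sub > threshold, na.rm = TRUE)
    if (all(viol == 0)) break
    step <- step + 1L
    cand <- keep[viol == max(viol)]
    if (length(cand) > 1) {
      mean_r <- rowMeans(sub[cand, , drop = FALSE], na.rm = TRUE)
      cand <- cand[mean_r == max(mean_r)]
      # remaining ties resolved by input order (keep preserves it)
    }
    victim <- cand[1]
    trace[[step]] <- tibble::tibble(
      step = step, feature = victim,
      n_violations = as.integer(viol[victim]),
      mean_abs_r = mean(sub[victim, ], na.rm = TRUE),
      partners = paste(keep[which(sub[victim, ] > threshold)], collapse = ",")
    )
    keep <- setdiff(keep, victim)
  }
  structure(list(retained = keep,
                 removed = vapply(trace, function(t) t$feature, character(1)),
                 trace = if (length(trace)) dplyr::bind_rows(trace)
                         else tibble::tibble(step = integer(), feature = character(),
                                             n_violations = integer(),
                                             mean_abs_r = double(),
                                             partners = character()),
                 threshold = threshold),
            class = "feature_reduction")
}

#' @export
print.feature_reduction <- function(x, ...) {
  cat(sprintf("<feature_reduction> threshold |r| > %g\n", x$threshold))
  if (length(x$removed) == 0) {
    cat("  nothing removed\n")
  } else {
    cat("  removed:", paste(x$removed, collapse = ", "), "\n")
  }
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Fit min-max scaling parameters
#'
#' @param table Data frame of feature values.
#' @param features Columns to fit; defaults to all numeric columns.
#' @return A `minmax_params` tibble (`feature`, `min`, `max`). Constant
#'   features are flagged with a warning; [apply_minmax()] maps them to 0.5.
#' @export
fit_minmax <- function(table, features = NULL) {
  table <- tibble::as_tibble(table)
  if (is.null(features)) {
    features <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  params <- tibble::tibble(
    feature = features,
    min = vapply(features, function(f) min(table[[f]]), double(1)),
    max = vapply(features, function(f) max(table[[f]]), double(1))
  )
  const <- params$feature[params$max == params$min]
  if (length(const) > 0) {
    warn(paste0("Constant feature(s) ", paste(const, collapse = ", "),
                ": min-max scaling will map all values to 0.5."))
  }
  structure(params, class = c("minmax_params", class(params)))
}

#' Apply min-max scaling
#'
#' Each fitted feature is mapped by `(x - min) / (max - min)`: the observed
#' fitting minimum goes to 0 and the maximum to 1. New data outside the
#' fitted range map outside \[0, 1\]; values are deliberately not clipped.
#'
#' @param params A `minmax_params` from [fit_minmax()].
#' @param table Data frame containing the fitted features.
#' @return The table with fitted feature columns replaced by scaled values.
#' @export
apply_minmax <- function(params, table) {
  stopifnot(inherits(params, "minmax_params"))
  table <- tibble::as_tibble(table)
  for (i in seq_len(nrow(params))) {
    f <- params$feature[i]
    if (!f %in% names(table)) {
      abort(sprintf("Feature '%s' missing from table.", f),
            class = "vacommittee_input_error")
    }
    rng <- params$max[i] - params$min[i]
    table[[f]] <- if (rng == 0) rep(0.5, nrow(table))
                  else (table[[f]] - params$min[i]) / rng
  }
  table
}

#' Rescale ratings between the \[-1, 1\] and \[0, 1\] scales
#'
#' Network targets live on \[0, 1\]; ratings are collected on \[-1, 1\].
#' `rescale_rating()` maps v to (v + 1) / 2; `unrescale_rating()` inverts it.
#'
#' @param v Numeric vector.
#' @return Numeric vector of the same length.
#' @export
rescale_rating <- function(v) {
  stopifnot(all(is.finite(v)))
  (v + 1) / 2
}

#' @rdname rescale_rating
#' @export
unrescale_rating <- function(v) {
  stopifnot(all(is.finite(v)))
  2 * v - 1
}

#' Baseline-correct a physiological feature
#'
#' Subtracts the feature value obtained during the white-noise baseline from
#' the value obtained during the excerpt. Missing baselines are an error,
#' never a silent zero.
#'
#' @param excerpt_value,baseline_value Numeric vectors of equal length.
#' @return `excerpt_value - baseline_value`.
#' @export
baseline_subtract <- function(excerpt_value, baseline_value) {
  if (length(excerpt_value) != length(baseline_value)) {
    abort("Excerpt and baseline values must have equal length.",
          class = "vacommittee_input_error")
  }
  if (anyNA(excerpt_value) || anyNA(baseline_value)) {
    abort("Missing excerpt or baseline value; baseline correction requires both.",
          class = "vacommittee_input_error")
  }
  excerpt_value - baseline_value
}

#' Feature-rating Pearson correlations
#'
#' Correlates each feature with the mean valence and arousal ratings,
#' reporting r, its degrees of freedom (n - 2) and the two-sided p value
#' from the t distribution.
#'
#' @param table Excerpt table containing the features and rating columns.
#' @param features Feature columns to correlate.
#' @param rating_cols Named character vector mapping dimension name to
#'   rating column.
#' @return Tibble with columns `feature`, `dimension`, `r`, `df`, `p`,
#'   `note` (`"zero variance"` where r is undefined).
#' @export
feature_rating_correlations <- function(table,
                                        features = c(audio_feature_names(),
                                                     physio_feature_names()),
                                        rating_cols = c(valence = "valence_mean",
                                                        arousal = "arousal_mean")) {
  table <- tibble::as_tibble(table)
  n <- nrow(table)
  if (n < 4) {
    abort("Need at least 4 excerpts for feature-rating correlations.",
          class = "vacommittee_input_error")
  }
  grid <- tidyr::expand_grid(feature = features,
                             dimension = names(rating_cols))
  purrr::pmap_dfr(grid, function(feature, dimension) {
    x <- table[[feature]]
    y <- table[[rating_cols[[dimension]]]]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble::tibble(feature = feature, dimension = dimension,
                            r = NA_real_, df = n - 2L, p = NA_real_,
                            note = "zero variance"))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble::tibble(feature = feature, dimension = dimension,
                   r = unname(ct$estimate), df = unname(ct$parameter),
                   p = ct$p.value, note = NA_character_)
  })
}

#' Preprocess a study for modeling
#'
#' Runs the full preparation: correlation-threshold reduction of the audio
#' features, the same check on the physiological features, min-max scaling
#' of the retained features, rescaling of mean ratings to \[0, 1\], and the
#' exploratory feature-rating correlations.
#'
#' @param study A `va_study`.
#' @param threshold Absolute-correlation threshold for feature removal.
#' @param scaling_scope `"all"` fits min-max bounds on the full excerpt
#'   table (the dataset-level convention this pipeline follows); `"train"`
#'   fits them on the training excerpts only, avoiding test-set leakage at
#'   the cost of departing from that convention. `"train"` requires
#'   `partition`.
#' @param partition Optional [make_partition()] result (needed for
#'   `scaling_scope = "train"`).
#' @return A `va_prepared` list: `excerpts` (scaled features plus
#'   `valence01`/`arousal01` targets), `audio_features` and
#'   `physio_features` retained, the two `feature_reduction` objects, the
#'   `minmax_params`, and `initial_correlations`.
#' @export
preprocess_study <- function(study, threshold = 0.8,
                             scaling_scope = c("all", "train"),
                             partition = NULL) {
  stopifnot(inherits(study, "va_study"))
  scaling_scope <- match.arg(scaling_scope)
  excerpts <- study$excerpts

  audio_red <- reduce_features(
    correlation_matrix(excerpts, audio_feature_names()), threshold)
  physio_red <- reduce_features(
    correlation_matrix(excerpts, physio_feature_names()), threshold)
  audio_keep <- audio_red$retained
  physio_keep <- physio_red$retained

  init_cor <- feature_rating_correlations(excerpts)

  fit_rows <- excerpts
  if (scaling_scope == "train") {
    if (is.null(partition)) {
      abort("`scaling_scope = \"train\"` requires a `partition`.",
            class = "vacommittee_config_error")
    }
    fit_rows <- excerpts[!excerpts$excerpt_id %in% partition$test_ids, ]
  }
  params <- fit_minmax(fit_rows, c(audio_keep, physio_keep))
  scaled <- apply_minmax(params, excerpts)
  scaled$valence01 <- rescale_rating(excerpts$valence_mean)
  scaled$arousal01 <- rescale_rating(excerpts$arousal_mean)

  structure(list(excerpts = scaled,
                 audio_features = audio_keep,
                 physio_features = physio_keep,
                 audio_reduction = audio_red,
                 physio_reduction = physio_red,
                 scaling = params,
                 initial_correlations = init_cor,
                 threshold = threshold,
                 scaling_scope = scaling_scope),
            class = "va_prepared")
}

#' @export
print.va_prepared <- function(x, ...) {
  cat(sprintf("<va_prepared> %d excerpts; %d audio + %d physio features retained\n",
              nrow(x$excerpts), length(x$audio_features),
              length(x$physio_features)))
  if (length(x$audio_reduction$removed))
    cat("  audio features removed:",
        paste(x$audio_reduction$removed, collapse = ", "), "\n")
  invisible(x)
}
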