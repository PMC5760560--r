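#' Pipeline configuration
#'
#' Bundles every stage's settings under one master seed. Stage seeds are
#' derived from the master seed through named substreams, so a single
#' integer reproduces the whole run while stages stay independently
#' re-runnable.
#'
#' @param seed Master seed.
#' @param generator A [generator_config()]; by default one seeded from the
#'   master seed's `simulate` substream.
#' @param threshold Correlation threshold for feature reduction.
#' @param scaling_scope `"all"` (dataset-level min-max fitting) or
#'   `"train"` (training excerpts only).
#' @param training A [training_config()]; per-network seeds are derived
#'   from the master seed, so `training$seed` is only a base.
#' @param committee_scope `"all"` fits the CMLR stacking regression on all
#'   excerpts (the convention this pipeline follows, acknowledging the
#'   train/test leakage it entails); `"train"` restricts it to the training
#'   excerpts.
#' @param forest A [forest_config()].
#' @param p_enter,p_remove Stepwise entry/removal p thresholds.
#' @param n_hidden Hidden units per network.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            generator = NULL,
                            threshold = 0.8,
                            scaling_scope = c("all", "train"),
                            training = training_config(),
                            committee_scope = c("all", "train"),
                            forest = NULL,
                            p_enter = 0.05, p_remove = 0.10,
                            n_hidden = 3L) {
  seed <- as.integer(seed)
  generator <- generator %||%
    generator_config(seed = substream_seed(seed, "simulate"))
  forest <- forest %||% forest_config(seed = substream_seed(seed, "forest"))
  structure(list(seed = seed, generator = generator, threshold = threshold,
                 scaling_scope = match.arg(scaling_scope),
                 training = training,
                 committee_scope = match.arg(committee_scope),
                 forest = forest, p_enter = p_enter, p_remove = p_remove,
                 n_hidden = as.integer(n_hidden)),
            class = "pipeline_config")
}

feature_matrix <- function(prep, ids, features) {
  rows <- match(ids, prep$excerpts$excerpt_id)
  if (anyNA(rows)) {
    abort("Partition references unknown excerpt ids.",
          class = "vacommittee_input_error")
  }
  as.matrix(prep$excerpts[rows, features, drop = FALSE])
}

target_vector <- function(prep, ids, dimension) {
  col <- paste0(substr(dimension, 1, nchar(dimension)), "01")
  prep$excerpts[[col]][match(ids, prep$excerpts$excerpt_id)]
}

#' Run the full modeling pipeline
#'
#' Executes simulate, preprocess, partition, network training, ensemble
#' evaluation, committee fitting, comparison arms and reporting in order.
#' Per (dimension, feature set), five fold networks are trained and used as
#' an unweighted-average ensemble; the perception and feeling ensembles are
#' then combined by the equal-weight committee (CMEA) and the
#' linear-regression committee (CMLR), whose coefficient magnitudes yield
#' the perception/feeling contribution percentages. Stepwise-regression
#' ensembles and random forests run as comparison arms on the same
#' partition, and everything is evaluated on the held-out test excerpts.
#'
#' The in-sample optimality invariant — CMLR RMSE no worse than CMEA RMSE
#' on the committee fitting set — is asserted on every run.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage artifact is
#'   written there (`excerpts.csv`, `ratings.csv`, `feature_reduction.json`,
#'   `initial_correlations.csv`, `partition.json`, per-network weight files,
#'   `committee.json`, stepwise selections, `report.csv`/`report.json`, and
#'   a run log with per-stage seeds, wall times, and convergence flags).
#' @param study Optional pre-built `va_study` (e.g. from [read_dataset()]);
#'   by default one is simulated from `config$generator`.
#' @param verbose Print stage progress.
#' @return A `va_pipeline` list with all stage results and the final
#'   `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         study = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t_all <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    if (verbose) message("stage: ", name)
    res <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "vacommittee_stage_error", parent = e)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  study <- stage("simulate", study %||% simulate_study(config$generator))

  partition <- stage("partition",
                     make_partition(study$excerpts,
                                    seed = substream_seed(config$seed, "partition")))

  prep <- stage("preprocess",
                preprocess_study(study, threshold = config$threshold,
                                 scaling_scope = config$scaling_scope,
                                 partition = partition))

  dims <- c("valence", "arousal")
  feature_sets <- list(audio = prep$audio_features,
                       physio = prep$physio_features)
  n_folds <- length(partition$folds)
  all_ids <- study$excerpts$excerpt_id
  test_ids <- partition$test_ids
  train_ids <- setdiff(all_ids, test_ids)

  networks <- stage("train", {
    out <- list()
    for (dim in dims) {
      out[[dim]] <- list()
      for (fs in names(feature_sets)) {
        feats <- feature_sets[[fs]]
        out[[dim]][[fs]] <- lapply(seq_len(n_folds), function(k) {
          ids <- training_set(partition, k)
          tc <- config$training
          tc$seed <- substream_seed(config$seed,
                                    paste("train", dim, fs, k))
          train_mlp(feature_matrix(prep, ids, feats),
                    target_vector(prep, ids, dim),
                    config = tc, n_hidden = config$n_hidden)
        })
      }
    }
    out
  })

  fold_rmse <- stage("fold_rmse", {
    grid <- tidyr::expand_grid(dimension = dims,
                               feature_set = names(feature_sets),
                               fold = seq_len(n_folds))
    purrr::pmap_dfr(grid, function(dimension, feature_set, fold) {
      ids <- partition$folds[[fold]]
      model <- networks[[dimension]][[feature_set]][[fold]]
      pred <- predict(model, feature_matrix(prep, ids,
                                            feature_sets[[feature_set]]))
      tibble::tibble(dimension = dimension, feature_set = feature_set,
                     fold = fold,
                     rmse = rmse(pred, target_vector(prep, ids, dimension)),
                     epochs = model$trace$epochs_run,
                     converged = model$trace$converged)
    })
  })

  ensembles <- stage("ensembles", {
    out <- list()
    for (dim in dims) {
      out[[dim]] <- list()
      for (fs in names(feature_sets)) {
        ens <- mlp_ensemble(networks[[dim]][[fs]], dim, fs)
        full_pred <- ensemble_predict(
          ens, feature_matrix(prep, all_ids, feature_sets[[fs]]))
        names(full_pred) <- all_ids
        out[[dim]][[fs]] <- list(
          ensemble = ens,
          outputs = full_pred,
          test_rmse = rmse(full_pred[test_ids],
                           target_vector(prep, test_ids, dim)))
      }
    }
    out
  })

  committees <- stage("committee", {
    fit_ids <- if (config$committee_scope == "all") all_ids else train_ids
    out <- list()
    for (dim in dims) {
      p_out <- ensembles[[dim]]$audio$outputs
      f_out <- ensembles[[dim]]$physio$outputs
      y_all <- setNames(target_vector(prep, all_ids, dim), all_ids)

      cmea_test <- cmea_predict(p_out[test_ids], f_out[test_ids])
      cmlr <- fit_cmlr(p_out[fit_ids], f_out[fit_ids], y_all[fit_ids],
                       dimension = dim)
      cmlr_test <- cmlr_predict(cmlr, p_out[test_ids], f_out[test_ids])

      cmlr_fit_rmse <- rmse(cmlr_predict(cmlr, p_out[fit_ids], f_out[fit_ids]),
                            y_all[fit_ids])
      cmea_fit_rmse <- rmse(cmea_predict(p_out[fit_ids], f_out[fit_ids]),
                            y_all[fit_ids])
      if (cmlr_fit_rmse > cmea_fit_rmse + 1e-9) {
        abort(sprintf(paste("CMLR in-sample RMSE (%0.4f) exceeds CMEA (%0.4f)",
                            "for %s; least-squares optimality violated."),
                      cmlr_fit_rmse, cmea_fit_rmse, dim),
              class = "vacommittee_numeric_error")
      }
      out[[dim]] <- list(
        cmea_rmse = rmse(cmea_test, y_all[test_ids]),
        cmlr = cmlr,
        cmlr_rmse = rmse(cmlr_test, y_all[test_ids]),
        cmlr_fit_rmse = cmlr_fit_rmse,
        cmea_fit_rmse = cmea_fit_rmse,
        contributions = contributions(cmlr))
    }
    out
  })

  stepwise <- stage("stepwise", {
    out <- list()
    for (dim in dims) {
      out[[dim]] <- list()
      for (fs in names(feature_sets)) {
        feats <- feature_sets[[fs]]
        resp <- paste0(dim, "01")
        models <- lapply(seq_len(n_folds), function(k) {
          ids <- training_set(partition, k)
          rows <- prep$excerpts[match(ids, prep$excerpts$excerpt_id),
                                c(resp, feats)]
          stepwise_forward(rows, resp, feats,
                           p_enter = config$p_enter,
                           p_remove = config$p_remove)
        })
        test_rows <- prep$excerpts[match(test_ids, prep$excerpts$excerpt_id),
                                   feats]
        pred <- stepwise_ensemble_predict(models, test_rows)
        out[[dim]][[fs]] <- list(
          models = models,
          n_models = sum(!vapply(models, is_no_model, logical(1))),
          no_model = is_no_model(pred),
          test_rmse = if (is_no_model(pred)) NA_real_
                      else rmse(pred, target_vector(prep, test_ids, dim)))
      }
    }
    out
  })

  forests <- stage("forest", {
    out <- list()
    for (dim in dims) {
      out[[dim]] <- list()
      for (fs in names(feature_sets)) {
        feats <- feature_sets[[fs]]
        fc <- config$forest
        fc$seed <- substream_seed(config$seed, paste("forest", dim, fs))
        model <- fit_forest(
          as.data.frame(feature_matrix(prep, train_ids, feats)),
          target_vector(prep, train_ids, dim), fc)
        pred <- forest_predict(
          model, as.data.frame(feature_matrix(prep, test_ids, feats)))
        out[[dim]][[fs]] <- list(
          model = model,
          test_rmse = rmse(pred, target_vector(prep, test_ids, dim)))
      }
    }
    out
  })

  report <- stage("report", {
    grid <- tidyr::expand_grid(dimension = dims,
                               feature_set = names(feature_sets))
    arms <- dplyr::bind_rows(
      purrr::pmap_dfr(grid, function(dimension, feature_set) {
        tibble::tibble(method = "neural network", dimension = dimension,
                       feature_set = feature_set,
                       rmse = ensembles[[dimension]][[feature_set]]$test_rmse,
                       n_models = n_folds, no_model = FALSE,
                       test_ids = list(test_ids))
      }),
      purrr::pmap_dfr(grid, function(dimension, feature_set) {
        s <- stepwise[[dimension]][[feature_set]]
        tibble::tibble(method = "stepwise regression", dimension = dimension,
                       feature_set = feature_set, rmse = s$test_rmse,
                       n_models = s$n_models, no_model = s$no_model,
                       test_ids = list(test_ids))
      }),
      purrr::pmap_dfr(grid, function(dimension, feature_set) {
        tibble::tibble(method = "random forest", dimension = dimension,
                       feature_set = feature_set,
                       rmse = forests[[dimension]][[feature_set]]$test_rmse,
                       n_models = 1L, no_model = FALSE,
                       test_ids = list(test_ids))
      }))
    committee_rows <- dplyr::bind_rows(lapply(dims, function(dim) {
      cc <- committees[[dim]]$contributions
      tibble::tibble(
        method = c("CMEA", "CMLR"), dimension = dim,
        rmse = c(committees[[dim]]$cmea_rmse, committees[[dim]]$cmlr_rmse),
        perc_pct = c(NA_real_, round_half_up(cc$perc_pct, 1)),
        feel_pct = c(NA_real_, round_half_up(cc$feel_pct, 1)))
    }))
    build_report(arms, committee_rows)
  })

  result <- structure(
    list(study = study, prep = prep, partition = partition,
         networks = networks, fold_rmse = fold_rmse, ensembles = ensembles,
         committees = committees, stepwise = stepwise, forests = forests,
         report = report, config = config,
         timings = tibble::tibble(stage = names(timings),
                                  seconds = unlist(timings)),
         total_seconds = as.numeric(difftime(Sys.time(), t_all, units = "secs"))),
    class = "va_pipeline")

  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

#' @export
print.va_pipeline <- function(x, ...) {
  cat(sprintf("<va_pipeline> seed %d, %.1f s total\n",
              x$config$seed, x$total_seconds))
  print(x$report)
  invisible(x)
}

network_to_json <- function(model) {
  list(shape = c(model$net$n_in, model$net$n_hidden, 1L),
       features = model$features,
       W_hi = model$net$W_hi, W_oh = model$net$W_oh,
       b_h = model$net$b_h, b_o = model$net$b_o,
       use_bias = model$net$use_bias,
       config = unclass(model$config),
       trace = list(epochs_run = model$trace$epochs_run,
                    converged = model$trace$converged,
                    final_mse = model$trace$mse[length(model$trace$mse)]))
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset(result$study, out_dir)
  readr::write_csv(result$prep$initial_correlations,
                   file.path(out_dir, "initial_correlations.csv"))
  jsonlite::write_json(
    list(threshold = result$prep$threshold,
         audio = list(removed = result$prep$audio_reduction$removed,
                      retained = result$prep$audio_reduction$retained,
                      trace = result$prep$audio_reduction$trace),
         physio = list(removed = result$prep$physio_reduction$removed,
                       retained = result$prep$physio_reduction$retained,
                       trace = result$prep$physio_reduction$trace)),
    file.path(out_dir, "feature_reduction.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_partition(result$partition, file.path(out_dir, "partition.json"))
  for (dim in names(result$networks)) {
    for (fs in names(result$networks[[dim]])) {
      models <- result$networks[[dim]][[fs]]
      for (k in seq_along(models)) {
        jsonlite::write_json(
          network_to_json(models[[k]]),
          file.path(out_dir, sprintf("network_%s_%s_fold%d.json", dim, fs, k)),
          auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
      }
      sw <- result$stepwise[[dim]][[fs]]
      jsonlite::write_json(
        lapply(sw$models, function(m) {
          list(no_model = m$no_model, selected = m$selected,
               coefficients = as.list(m$coefficients))
        }),
        file.path(out_dir, sprintf("stepwise_%s_%s.json", dim, fs)),
        auto_unbox = TRUE, digits = NA)
    }
  }
  jsonlite::write_json(
    lapply(result$committees, function(cm) {
      cc <- cm$contributions
      list(b_perc = cm$cmlr$b_perc, b_feel = cm$cmlr$b_feel,
           intercept = cm$cmlr$intercept,
           perc_pct = round_half_up(cc$perc_pct, 1),
           feel_pct = round_half_up(cc$feel_pct, 1),
           fit_scope = result$config$committee_scope,
           n_fit = cm$cmlr$n,
           cmea_test_rmse = cm$cmea_rmse, cmlr_test_rmse = cm$cmlr_rmse)
    }),
    file.path(out_dir, "committee.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_report(result$report, out_dir)
  log_lines <- c(
    sprintf("master seed: %d", result$config$seed),
    sprintf("stage %s: %.2f s", result$timings$stage, result$timings$seconds),
    sprintf("network %s/%s fold %d: epochs %d, converged %s",
            result$fold_rmse$dimension, result$fold_rmse$feature_set,
            result$fold_rmse$fold, result$fold_rmse$epochs,
            result$fold_rmse$converged))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
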