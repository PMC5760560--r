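#' Summarize per-fold RMSE values
#'
#' Aggregates the five per-fold test RMSEs of an ensemble into their mean
#' and standard error, the summary printed beneath the per-fold tables.
#'
#' @param rmse_values Numeric vector of fold RMSEs.
#' @return Tibble with `mean` and `se` (`sd / sqrt(n)`).
#' @export
#' @examples
#' summarize_folds(c(0.27, 0.21, 0.16, 0.26, 0.16))
summarize_folds <- function(rmse_values) {
  stopifnot(is.numeric(rmse_values), length(rmse_values) >= 1)
  tibble::tibble(mean = mean(rmse_values),
                 se = sd(rmse_values) / sqrt(length(rmse_values)))
}

#' Build the cross-method results report
#'
#' Collects the test-set RMSE of every arm (network ensembles, stepwise
#' regression ensembles, random forests) for each emotion dimension and
#' feature set, plus the committee-machine rows, into one grid. "No model"
#' outcomes are carried as such, never as zeros.
#'
#' @param arms Tibble with columns `method`, `dimension`, `feature_set`,
#'   `rmse` (`NA` allowed where `no_model`), `n_models`, `no_model`
#'   (logical), `test_ids` (list-column of the evaluation excerpt ids).
#' @param committee Tibble with columns `method` (`"CMEA"`/`"CMLR"`),
#'   `dimension`, `rmse`, and optionally `perc_pct`, `feel_pct`.
#' @return A `va_report` tibble.
#' @export
build_report <- function(arms, committee = NULL) {
  arms <- tibble::as_tibble(arms)
  required <- c("method", "dimension", "feature_set", "rmse", "no_model")
  missing <- setdiff(required, names(arms))
  if (length(missing) > 0) {
    abort(paste0("Report arms are missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "vacommittee_input_error")
  }
  if ("test_ids" %in% names(arms)) {
    sets <- unique(lapply(arms$test_ids, sort))
    if (length(sets) > 1) {
      abort("All arms must be evaluated on the same test excerpts.",
            class = "vacommittee_input_error")
    }
    arms$test_ids <- NULL
  }
  if (any(arms$rmse[!arms$no_model] < 0, na.rm = TRUE)) {
    abort("RMSE cells must be non-negative.",
          class = "vacommittee_input_error")
  }
  if (!"n_models" %in% names(arms)) arms$n_models <- NA_integer_
  out <- arms[c("method", "dimension", "feature_set", "rmse",
                "n_models", "no_model")]
  if (!is.null(committee)) {
    committee <- tibble::as_tibble(committee)
    committee$feature_set <- "audio+physio"
    committee$no_model <- FALSE
    if (!"n_models" %in% names(committee)) committee$n_models <- NA_integer_
    out <- dplyr::bind_rows(
      out,
      committee[intersect(c("method", "dimension", "feature_set", "rmse",
                            "n_models", "no_model", "perc_pct", "feel_pct"),
                          names(committee))])
  }
  structure(out, class = c("va_report", class(out)))
}

#' Render report cells for display
#'
#' @param report A `va_report`.
#' @return The report with a character `display` column in which "no model"
#'   outcomes read `"no model"` and RMSEs are shown to two decimals.
#' @export
format_report <- function(report) {
  stopifnot(inherits(report, "va_report"))
  dplyr::mutate(tibble::as_tibble(report),
                display = ifelse(.data$no_model, "no model",
                                 sprintf("%.2f", .data$rmse)))
}

#' @export
print.va_report <- function(x, ...) {
  cat("<va_report> test-set RMSE by method\n")
  print(tibble::as_tibble(format_report(x)), n = Inf)
  invisible(x)
}

#' Write the report as CSV and JSON artifacts
#'
#' @param report A `va_report`.
#' @param dir Output directory.
#' @return Invisibly, the file paths.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "report.csv")
  js <- file.path(dir, "report.json")
  readr::write_csv(format_report(report), csv, na = "")
  jsonlite::write_json(format_report(report), js, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  invisible(c(csv = csv, json = js))
}
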