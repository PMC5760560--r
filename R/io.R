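#' Write a study to delimited text files
#'
#' Writes `excerpts.csv` (one row per excerpt: id, genre, 12 audio features,
#' 5 physiological features, 5 baseline columns, mean ratings, latent ground
#' truth where present) and `ratings.csv` (participant-level ratings) into
#' `path`. Values round-trip at full precision through [read_dataset()].
#'
#' @param study A `va_study` from [simulate_study()] or [read_dataset()].
#' @param path Directory to write into; created if missing.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(study, path) {
  stopifnot(inherits(study, "va_study"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) {
    abort(sprintf("Cannot create output directory '%s'.", path),
          class = "vacommittee_io_error")
  }
  files <- c(excerpts = file.path(path, "excerpts.csv"),
             ratings = file.path(path, "ratings.csv"))
  readr::write_csv(study$excerpts, files[["excerpts"]])
  readr::write_csv(study$ratings, files[["ratings"]])
  invisible(files)
}

#' Read a study back from delimited text files
#'
#' @param path Directory containing `excerpts.csv` and `ratings.csv`.
#' @return A `va_study` list. Latent columns are optional (absent for
#'   ingested real data); the `config` element is `NULL` for ingested data.
#' @export
read_dataset <- function(path) {
  fe <- file.path(path, "excerpts.csv")
  fr <- file.path(path, "ratings.csv")
  if (!file.exists(fe)) {
    abort(sprintf("Missing '%s'; run the simulate stage (or write_dataset()) first.", fe),
          class = "vacommittee_io_error")
  }
  excerpts <- readr::read_csv(fe, show_col_types = FALSE)
  required <- c("excerpt_id", "genre", audio_feature_names(),
                physio_feature_names(), "valence_mean", "arousal_mean")
  missing <- setdiff(required, names(excerpts))
  if (length(missing) > 0) {
    abort(paste0("excerpts.csv is missing required columns: ",
                 paste(missing, collapse = ", ")),
          class = "vacommittee_io_error")
  }
  feat <- c(audio_feature_names(), physio_feature_names(),
            "valence_mean", "arousal_mean")
  if (anyNA(excerpts[feat])) {
    abort("excerpts.csv contains missing feature or rating values; ingest rejects incomplete data.",
          class = "vacommittee_io_error")
  }
  if (any(abs(excerpts$valence_mean) > 1) || any(abs(excerpts$arousal_mean) > 1)) {
    abort("Mean ratings must lie in [-1, 1].", class = "vacommittee_io_error")
  }
  ratings <- NULL
  if (file.exists(fr)) {
    ratings <- readr::read_csv(fr, show_col_types = FALSE)
  }
  structure(list(excerpts = excerpts, ratings = ratings,
                 design = if (!is.null(ratings))
                   ratings[c("participant_id", "excerpt_id")],
                 config = NULL),
            class = "va_study")
}
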