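#' Train/test and cross-validation layout
#'
#' Splits the excerpts into a genre-balanced 16-excerpt test set (4 per
#' genre), 4 "always-train" excerpts (1 per genre) that join every training
#' set but are never used as a validation fold, and 5 cross-validation folds
#' of 8 (2 per genre). Each fold's network trains on the other 4 folds plus
#' the always-train excerpts: 36 excerpts, 9 per genre. Membership is drawn
#' uniformly at random within genre strata, deterministically from the seed.
#'
#' @param excerpts Excerpt table with `excerpt_id` and `genre` columns.
#' @param seed Integer seed.
#' @param n_folds Number of cross-validation folds.
#' @param test_per_genre,always_per_genre Per-genre counts for the test and
#'   always-train sets.
#' @return A `va_partition`: `test_ids`, `always_train_ids`, `folds` (list
#'   of id vectors), `genre_of` lookup, and the seed.
#' @export
#' @examples
#' study <- simulate_study(generator_config(seed = 2))
#' p <- make_partition(study$excerpts, seed = 2)
#' lengths(p$folds)
make_partition <- function(excerpts, seed, n_folds = 5L,
                           test_per_genre = 4L, always_per_genre = 1L) {
  stopifnot(all(c("excerpt_id", "genre") %in% names(excerpts)))
  genres <- unique(excerpts$genre)
  counts <- table(excerpts$genre)
  if (length(unique(counts)) != 1) {
    abort("All genres must contain the same number of excerpts.",
          class = "vacommittee_config_error")
  }
  per_genre <- unname(counts[1])
  fold_per_genre <- (per_genre - test_per_genre - always_per_genre) / n_folds
  if (fold_per_genre < 1 || fold_per_genre != round(fold_per_genre)) {
    abort(sprintf(paste("Infeasible layout: %d excerpts per genre cannot split",
                        "into %d test + %d always-train + %d equal folds."),
                  per_genre, test_per_genre, always_per_genre, n_folds),
          class = "vacommittee_config_error")
  }
  fold_per_genre <- as.integer(fold_per_genre)

  set.seed(substream_seed(seed, "partition"))
  test_ids <- character(0)
  always_ids <- character(0)
  folds <- replicate(n_folds, character(0), simplify = FALSE)
  for (g in genres) {
    ids <- sample(excerpts$excerpt_id[excerpts$genre == g])
    test_ids <- c(test_ids, ids[seq_len(test_per_genre)])
    ids <- ids[-seq_len(test_per_genre)]
    always_ids <- c(always_ids, ids[seq_len(always_per_genre)])
    ids <- ids[-seq_len(always_per_genre)]
    for (k in seq_len(n_folds)) {
      folds[[k]] <- c(folds[[k]], ids[(k - 1L) * fold_per_genre + seq_len(fold_per_genre)])
    }
  }
  structure(list(test_ids = sort(test_ids),
                 always_train_ids = sort(always_ids),
                 folds = lapply(folds, sort),
                 genre_of = setNames(excerpts$genre, excerpts$excerpt_id),
                 seed = as.integer(seed)),
            class = "va_partition")
}

#' Training excerpts for one cross-validation fold
#'
#' @param partition A `va_partition`.
#' @param fold_index Which fold's network (1-based); its training set is the
#'   other folds plus the always-train excerpts.
#' @return Character vector of excerpt ids (36 at the default layout).
#' @export
training_set <- function(partition, fold_index) {
  stopifnot(inherits(partition, "va_partition"))
  n <- length(partition$folds)
  if (!is.numeric(fold_index) || length(fold_index) != 1 ||
      fold_index < 1 || fold_index > n || fold_index != round(fold_index)) {
    abort(sprintf("`fold_index` must be an integer in 1..%d.", n),
          class = "vacommittee_input_error")
  }
  sort(c(unlist(partition$folds[-fold_index], use.names = FALSE),
         partition$always_train_ids))
}

#' @export
print.va_partition <- function(x, ...) {
  cat(sprintf("<va_partition> test %d | always-train %d | %d folds of %d (seed %d)\n",
              length(x$test_ids), length(x$always_train_ids),
              length(x$folds), length(x$folds[[1]]), x$seed))
  invisible(x)
}

#' Serialize / restore a partition as JSON
#'
#' @param partition A `va_partition`.
#' @param path File path for `partition.json`.
#' @return `write_partition()` returns the path invisibly;
#'   `read_partition()` returns a `va_partition`.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "va_partition"))
  obj <- list(test_ids = partition$test_ids,
              always_train_ids = partition$always_train_ids,
              folds = partition$folds,
              genre_of = as.list(partition$genre_of),
              seed = partition$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(test_ids = obj$test_ids,
                 always_train_ids = obj$always_train_ids,
                 folds = if (is.list(obj$folds)) obj$folds
                         else apply(obj$folds, 1, identity, simplify = FALSE),
                 genre_of = unlist(obj$genre_of),
                 seed = as.integer(obj$seed)),
            class = "va_partition")
}
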