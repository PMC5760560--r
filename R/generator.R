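#' Configuration for the synthetic study generator
#'
#' Describes the design of the listening study the generator emulates:
#' 60 music excerpts spread evenly over 4 genres, rated by 60 participants,
#' each of whom hears 12 excerpts (3 per genre) so that every excerpt is
#' rated by exactly 12 participants. Each excerpt carries 12 audio features
#' (with a strongly inter-correlated spectral block) and 5 baseline-corrected
#' physiological features. Latent valence and arousal are mixtures of a
#' smooth function of the audio features (the "perception" channel) and a
#' smooth function of the physiological features (the "feeling" channel).
#'
#' @param n_excerpts Total number of excerpts.
#' @param genres Character vector of genre labels.
#' @param excerpts_per_genre Excerpts in each genre.
#' @param n_participants Number of raters recruited.
#' @param excerpts_per_participant Excerpts heard by each participant;
#'   must be divisible by the number of genres.
#' @param raters_per_excerpt Number of participants hearing each excerpt.
#' @param collinear_block Names of the four spectral features generated from
#'   a shared latent factor.
#' @param collinear_r Target pairwise Pearson correlation within the
#'   spectral block (population value).
#' @param mixing Named list with elements `valence` and `arousal`, each a
#'   numeric pair `c(w_perc, w_feel)` summing to 1: the fraction of the
#'   latent emotion signal carried by the audio vs physiology channel.
#' @param rating_noise_sd Standard deviation of per-participant rating noise
#'   on the \[-1, 1\] rating scale.
#' @param seed Integer seed; all draws flow from named substreams of it.
#'
#' @return A `generator_config` list, validated.
#' @export
#' @examples
#' cfg <- generator_config(seed = 7)
#' cfg$n_excerpts
generator_config <- function(n_excerpts = 60L,
                             genres = c("Blues", "Metal", "Pop", "RnB"),
                             excerpts_per_genre = 15L,
                             n_participants = 60L,
                             excerpts_per_participant = 12L,
                             raters_per_excerpt = 12L,
                             collinear_block = c("centroid", "spread",
                                                 "rolloff", "brightness"),
                             collinear_r = 0.9,
                             mixing = list(valence = c(w_perc = 0.80, w_feel = 0.20),
                                           arousal = c(w_perc = 0.45, w_feel = 0.55)),
                             rating_noise_sd = 0.3,
                             seed = 1L) {
  cfg <- list(
    n_excerpts = as.integer(n_excerpts),
    genres = as.character(genres),
    excerpts_per_genre = as.integer(excerpts_per_genre),
    n_participants = as.integer(n_participants),
    excerpts_per_participant = as.integer(excerpts_per_participant),
    raters_per_excerpt = as.integer(raters_per_excerpt),
    audio_feature_names = audio_feature_names(),
    physio_feature_names = physio_feature_names(),
    collinear_block = collinear_block,
    collinear_r = collinear_r,
    mixing = mixing,
    rating_noise_sd = rating_noise_sd,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

#' The 12 audio feature names
#' @return Character vector of length 12.
#' @export
audio_feature_names <- function() {
  c("rms", "lowenergy", "eventdensity", "tempo", "pulseclarity",
    "centroid", "spread", "rolloff", "brightness", "irregularity",
    "inharmonicity", "mode")
}

#' The 5 physiological feature names
#' @return Character vector of length 5.
#' @export
physio_feature_names <- function() {
  c("HR", "Resp", "SCL", "Zyg", "Corr")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_excerpts != length(cfg$genres) * cfg$excerpts_per_genre) {
    abort("`n_excerpts` must equal `length(genres) * excerpts_per_genre`.",
          class = "vacommittee_config_error")
  }
  if (cfg$n_participants * cfg$excerpts_per_participant !=
      cfg$n_excerpts * cfg$raters_per_excerpt) {
    abort(paste("Rating slots do not balance:",
                "`n_participants * excerpts_per_participant` must equal",
                "`n_excerpts * raters_per_excerpt`."),
          class = "vacommittee_config_error")
  }
  if (cfg$excerpts_per_participant %% length(cfg$genres) != 0L) {
    abort("`excerpts_per_participant` must be divisible by the number of genres.",
          class = "vacommittee_config_error")
  }
  for (dim in c("valence", "arousal")) {
    w <- cfg$mixing[[dim]]
    if (is.null(w) || length(w) != 2L || any(w < 0) || any(w > 1) ||
        abs(sum(w) - 1) > 1e-9) {
      abort(sprintf("`mixing$%s` must be two weights in [0, 1] summing to 1.", dim),
            class = "vacommittee_config_error")
    }
  }
  if (!all(cfg$collinear_block %in% cfg$audio_feature_names)) {
    abort("`collinear_block` must name audio features.",
          class = "vacommittee_config_error")
  }
  if (cfg$collinear_r <= 0 || cfg$collinear_r >= 1) {
    abort("`collinear_r` must lie in (0, 1).",
          class = "vacommittee_config_error")
  }
  if (cfg$rating_noise_sd < 0) {
    abort("`rating_noise_sd` must be non-negative.",
          class = "vacommittee_config_error")
  }
  invisible(cfg)
}

excerpt_ids <- function(cfg) {
  sprintf("ex%03d", seq_len(cfg$n_excerpts))
}

participant_ids <- function(cfg) {
  sprintf("p%03d", seq_len(cfg$n_participants))
}

#' Build the participant-by-excerpt rating design
#'
#' Constructs a balanced incidence: every participant rates
#' `excerpts_per_participant` excerpts, split evenly over genres, and every
#' excerpt is rated by exactly `raters_per_excerpt` participants. Within each
#' genre the incidence is a cyclic block design with seeded random relabeling
#' of participants and excerpts, so the assignment is a deterministic
#' function of the seed.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `participant_id`, `excerpt_id`, `genre`;
#'   one row per rating slot.
#' @export
#' @examples
#' d <- build_design(generator_config(seed = 1))
#' table(table(d$excerpt_id))  # every excerpt has 12 raters
build_design <- function(config) {
  validate_generator_config(config)
  n_genres <- length(config$genres)
  k <- config$excerpts_per_participant %/% n_genres # excerpts per participant per genre
  E <- config$excerpts_per_genre
  P <- config$n_participants
  R <- config$raters_per_excerpt
  if (k > E) {
    abort("Infeasible design: participants need more distinct excerpts per genre than exist.",
          class = "vacommittee_config_error")
  }
  ex_ids <- excerpt_ids(config)
  genre_of <- rep(config$genres, each = config$excerpts_per_genre)
  p_ids <- participant_ids(config)

  set.seed(substream_seed(config$seed, "design"))
  rows <- lapply(seq_along(config$genres), function(gi) {
    ids_g <- sample(ex_ids[genre_of == config$genres[gi]]) # seeded relabeling
    p_order <- sample(seq_len(P))
    slots <- lapply(seq_len(P), function(i) {
      p <- p_order[i] # cyclic assignment over permuted participants
      idx <- ((i - 1L) * k + seq_len(k) - 1L) %% E + 1L
      tibble::tibble(participant_id = p_ids[p],
                     excerpt_id = ids_g[idx],
                     genre = config$genres[gi])
    })
    dplyr::bind_rows(slots)
  })
  design <- dplyr::bind_rows(rows)

  counts <- table(design$excerpt_id)
  if (length(counts) != config$n_excerpts || any(counts != R)) {
    abort(paste("Infeasible design: the cyclic construction cannot balance",
                "these counts (each excerpt must receive exactly",
                R, "raters)."),
          class = "vacommittee_config_error")
  }
  dplyr::arrange(design, .data$participant_id, .data$excerpt_id)
}

# Fixed smooth generative maps from features to the latent emotion channels.
# Degree-2 polynomials squashed by tanh into [-1, 1]; coefficients are part
# of the generator's published definition.
g_audio_valence <- function(a) {
  tanh(0.9 * (2 * a$mode - 1) - 0.55 * a$brightness - 0.45 * a$eventdensity +
         0.25 * a$rms * a$lowenergy - 0.20 * a$irregularity^2 + 0.2)
}

g_audio_arousal <- function(a) {
  tanh(0.8 * a$eventdensity + 0.5 * a$tempo + 0.35 * a$brightness +
         0.25 * a$rms + 0.15 * a$pulseclarity^2 - 0.1)
}

h_physio_valence <- function(p) {
  tanh(0.45 * p$Zyg - 0.45 * p$Corr - 0.10 * p$Corr^2 + 0.1)
}

h_physio_arousal <- function(p) {
  tanh(0.45 * p$HR + 0.30 * p$SCL + 0.25 * p$Resp + 0.10 * p$HR * p$SCL - 0.1)
}

#' Generate the excerpt-level feature table
#'
#' Draws 12 audio features per excerpt — the four spectral features
#' (`centroid`, `spread`, `rolloff`, `brightness`) share one latent factor so
#' their pairwise correlation is `collinear_r`; the rest are independent —
#' and 5 baseline-corrected physiological features coupled to a latent
#' affective state (`Zyg` up / `Corr` down with valence; `HR`, `Resp`, `SCL`
#' up with arousal). Latent valence and arousal are convex mixtures
#' `w_perc * g(audio) + w_feel * h(physio)` of fixed smooth channel maps, so
#' they always lie in \[-1, 1\].
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per excerpt: `excerpt_id`, `genre`, the 12
#'   audio features, the 5 physiological features, 5 `baseline_*` columns
#'   (the white-noise baseline levels that were subtracted), and
#'   `latent_valence`, `latent_arousal`.
#' @export
generate_excerpts <- function(config) {
  validate_generator_config(config)
  n <- config$n_excerpts
  genre <- rep(config$genres, each = config$excerpts_per_genre)

  set.seed(substream_seed(config$seed, "audio"))
  jitter_sd <- sqrt(1 / config$collinear_r - 1)
  f_spec <- rnorm(n)
  audio <- tibble::tibble(
    rms = rnorm(n),
    lowenergy = rnorm(n),
    eventdensity = rnorm(n),
    tempo = rnorm(n),
    pulseclarity = rnorm(n),
    centroid = f_spec + jitter_sd * rnorm(n),
    spread = f_spec + jitter_sd * rnorm(n),
    rolloff = f_spec + jitter_sd * rnorm(n),
    brightness = f_spec + jitter_sd * rnorm(n),
    irregularity = rnorm(n),
    inharmonicity = rnorm(n),
    mode = stats::pnorm(rnorm(n))
  )
  # modest genre colouring of rhythm/dynamics features (recycled over genres)
  shifts <- data.frame(tempo = c(-0.4, 0.6, 0.2, -0.2),
                       eventdensity = c(-0.3, 0.5, 0.0, -0.1),
                       rms = c(-0.2, 0.5, 0.1, 0.0))
  gi <- (match(genre, config$genres) - 1L) %% 4L + 1L
  audio$tempo <- audio$tempo + shifts$tempo[gi]
  audio$eventdensity <- audio$eventdensity + shifts$eventdensity[gi]
  audio$rms <- audio$rms + shifts$rms[gi]

  set.seed(substream_seed(config$seed, "physio"))
  p_val <- rnorm(n) # latent affective state expressed in physiology
  p_aro <- rnorm(n)
  physio <- tibble::tibble(
    HR = 0.75 * p_aro + 0.66 * rnorm(n),
    Resp = 0.65 * p_aro + 0.76 * rnorm(n),
    SCL = 0.80 * p_aro + 0.60 * rnorm(n),
    Zyg = 0.85 * p_val + 0.55 * rnorm(n),
    Corr = -0.85 * p_val + 0.55 * rnorm(n)
  )
  baseline <- tibble::tibble(
    baseline_HR = rnorm(n, 2.0, 0.15),
    baseline_Resp = rnorm(n, 1.5, 0.10),
    baseline_SCL = rnorm(n, 3.0, 0.20),
    baseline_Zyg = rnorm(n, 1.0, 0.10),
    baseline_Corr = rnorm(n, 1.0, 0.10)
  )

  w_v <- config$mixing$valence
  w_a <- config$mixing$arousal
  latent_valence <- w_v[[1]] * g_audio_valence(audio) +
    w_v[[2]] * h_physio_valence(physio)
  latent_arousal <- w_a[[1]] * g_audio_arousal(audio) +
    w_a[[2]] * h_physio_arousal(physio)

  dplyr::bind_cols(
    tibble::tibble(excerpt_id = excerpt_ids(config), genre = genre),
    audio, physio, baseline,
    tibble::tibble(latent_valence = latent_valence,
                   latent_arousal = latent_arousal)
  )
}

#' Simulate per-participant ratings and excerpt-level means
#'
#' Each (participant, excerpt) rating is the excerpt's latent value plus
#' participant noise, clipped to the \[-1, 1\] rating grid. Excerpt means are
#' the average over that excerpt's raters and are appended to the excerpt
#' table as `valence_mean` / `arousal_mean`.
#'
#' @param design Output of [build_design()] over the same config.
#' @param excerpts Output of [generate_excerpts()].
#' @param config The [generator_config()] used for both.
#' @return List with elements `ratings` (tibble: `participant_id`,
#'   `excerpt_id`, `valence`, `arousal`) and `excerpts` (input table with
#'   mean-rating columns added).
#' @export
generate_ratings <- function(design, excerpts, config) {
  validate_generator_config(config)
  if (!all(design$excerpt_id %in% excerpts$excerpt_id)) {
    abort("`design` references excerpts not present in `excerpts`.",
          class = "vacommittee_config_error")
  }
  set.seed(substream_seed(config$seed, "ratings"))
  idx <- match(design$excerpt_id, excerpts$excerpt_id)
  m <- nrow(design)
  ratings <- tibble::tibble(
    participant_id = design$participant_id,
    excerpt_id = design$excerpt_id,
    valence = clip(excerpts$latent_valence[idx] +
                     rnorm(m, sd = config$rating_noise_sd)),
    arousal = clip(excerpts$latent_arousal[idx] +
                     rnorm(m, sd = config$rating_noise_sd))
  )
  means <- ratings |>
    dplyr::group_by(.data$excerpt_id) |>
    dplyr::summarise(valence_mean = mean(.data$valence),
                     arousal_mean = mean(.data$arousal), .groups = "drop")
  excerpts <- excerpts |>
    dplyr::select(-dplyr::any_of(c("valence_mean", "arousal_mean"))) |>
    dplyr::left_join(means, by = "excerpt_id") |>
    dplyr::relocate(dplyr::all_of(c("valence_mean", "arousal_mean")),
                    .before = "latent_valence")
  list(ratings = ratings, excerpts = excerpts)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [build_design()], [generate_excerpts()] and
#' [generate_ratings()] under one config.
#'
#' @param config A [generator_config()].
#' @return A `va_study` list: `excerpts` (one row per excerpt with features,
#'   mean ratings and latent ground truth), `ratings` (one row per
#'   participant-excerpt pair), `design`, and the `config`.
#' @export
#' @examples
#' study <- simulate_study(generator_config(seed = 3))
#' dim(study$excerpts)
simulate_study <- function(config = generator_config()) {
  design <- build_design(config)
  excerpts <- generate_excerpts(config)
  rated <- generate_ratings(design, excerpts, config)
  structure(list(excerpts = rated$excerpts, ratings = rated$ratings,
                 design = design, config = config),
            class = "va_study")
}

#' @export
print.va_study <- function(x, ...) {
  cat(sprintf("<va_study> %d excerpts in %d genres, %d participants, %d ratings\n",
              nrow(x$excerpts), length(unique(x$excerpts$genre)),
              length(unique(x$ratings$participant_id)), nrow(x$ratings)))
  invisible(x)
}
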