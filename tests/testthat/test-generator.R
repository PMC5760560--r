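test_that("generator config invariants are enforced", {
  expect_error(generator_config(n_excerpts = 59),
               class = "vacommittee_config_error")
  expect_error(generator_config(raters_per_excerpt = 11),
               class = "vacommittee_config_error")
  expect_error(
    generator_config(mixing = list(valence = c(0.6, 0.6),
                                   arousal = c(0.5, 0.5))),
    class = "vacommittee_config_error")
  expect_silent(generator_config())
})

test_that("rating design is balanced: 12 raters per excerpt, 12 excerpts per participant, 3 per genre", {
  d <- build_design(generator_config(seed = 7))
  expect_true(all(table(d$excerpt_id) == 12))
  expect_true(all(table(d$participant_id) == 12))
  expect_true(all(table(d$participant_id, d$genre) == 3))
})

test_that("design balance holds across many seeds", {
  for (s in 1:20) {
    d <- build_design(generator_config(seed = s))
    expect_true(all(table(d$excerpt_id) == 12))
    expect_true(all(table(d$participant_id) == 12))
    expect_true(all(table(d$participant_id, d$genre) == 3))
  }
})

test_that("a small forced layout gives the expected incidence", {
  d <- build_design(generator_config(n_excerpts = 4, genres = "only",
                                     excerpts_per_genre = 4,
                                     n_participants = 4,
                                     excerpts_per_participant = 2,
                                     raters_per_excerpt = 2))
  expect_equal(nrow(d), 8)
  expect_true(all(table(d$excerpt_id) == 2))
  expect_true(all(table(d$participant_id) == 2))
})

test_that("design and excerpts are deterministic in the seed", {
  c5 <- generator_config(seed = 5)
  expect_identical(build_design(c5), build_design(c5))
  expect_identical(generate_excerpts(c5), generate_excerpts(c5))
  d5 <- build_design(c5)
  d6 <- build_design(generator_config(seed = 6))
  expect_false(identical(d5, d6))
})

test_that("spectral block is collinear and other audio pairs are not", {
  e <- default_study$excerpts
  block <- c("centroid", "spread", "rolloff", "brightness")
  r <- cor(as.matrix(e[audio_feature_names()]))
  block_pairs <- abs(r[block, block][upper.tri(diag(4))])
  expect_true(all(block_pairs > 0.8))
  r_rest <- r
  r_rest[block, block] <- 0
  diag(r_rest) <- 0
  expect_true(all(abs(r_rest) < 0.8))
})

test_that("pure-perception mixing makes latent valence a function of audio alone", {
  cfg <- generator_config(seed = 11,
                          mixing = list(valence = c(1, 0), arousal = c(0, 1)))
  e <- generate_excerpts(cfg)
  expect_equal(e$latent_valence, vacommittee:::g_audio_valence(e),
               tolerance = 1e-12)
  expect_equal(e$latent_arousal, vacommittee:::h_physio_arousal(e),
               tolerance = 1e-12)
  # physiology-coupled arousal changes when the physiological state changes
  e2 <- generate_excerpts(
    generator_config(seed = 12,
                     mixing = list(valence = c(1, 0), arousal = c(0, 1))))
  expect_false(isTRUE(all.equal(e$latent_arousal, e2$latent_arousal)))
})

test_that("latents and mean ratings stay within the rating scale", {
  cfg <- generator_config(seed = 13, rating_noise_sd = 5)
  study <- simulate_study(cfg)
  expect_true(all(abs(study$ratings$valence) <= 1))
  expect_true(all(abs(study$ratings$arousal) <= 1))
  expect_true(all(abs(study$excerpts$latent_valence) <= 1))
  expect_true(all(abs(study$excerpts$valence_mean) <= 1))
})

test_that("zero rating noise reproduces the latent values exactly", {
  study <- simulate_study(generator_config(seed = 3, rating_noise_sd = 0))
  expect_equal(study$excerpts$valence_mean, study$excerpts$latent_valence,
               tolerance = 1e-12)
  expect_equal(study$excerpts$arousal_mean, study$excerpts$latent_arousal,
               tolerance = 1e-12)
})

test_that("averaging over 12 raters shrinks rating error about sqrt(12)-fold", {
  devs_mean <- c()
  devs_single <- c()
  for (s in 1:10) {
    study <- simulate_study(generator_config(seed = s, rating_noise_sd = 0.3))
    devs_mean <- c(devs_mean,
                   study$excerpts$valence_mean - study$excerpts$latent_valence)
    idx <- match(study$ratings$excerpt_id, study$excerpts$excerpt_id)
    devs_single <- c(devs_single,
                     study$ratings$valence - study$excerpts$latent_valence[idx])
  }
  ratio <- mean(abs(devs_single)) / mean(abs(devs_mean))
  expect_gt(ratio, sqrt(12) * 0.85)
  expect_lt(ratio, sqrt(12) * 1.15)
})

test_that("dataset round-trips through CSV at full precision", {
  dir <- withr::local_tempdir()
  write_dataset(default_study, dir)
  back <- read_dataset(dir)
  expect_equal(as.data.frame(back$excerpts),
               as.data.frame(default_study$excerpts), tolerance = 1e-12)
  expect_equal(as.data.frame(back$ratings),
               as.data.frame(default_study$ratings), tolerance = 1e-12)
  # schema contract and row counts
  header <- strsplit(readLines(file.path(dir, "excerpts.csv"), n = 1), ",")[[1]]
  expect_true(all(c("excerpt_id", "genre", audio_feature_names(),
                    physio_feature_names(), "valence_mean", "arousal_mean",
                    "latent_valence", "latent_arousal") %in% header))
  expect_length(readLines(file.path(dir, "excerpts.csv")), 61)
})

test_that("ingest rejects incomplete data", {
  dir <- withr::local_tempdir()
  write_dataset(default_study, dir)
  e <- readr::read_csv(file.path(dir, "excerpts.csv"), show_col_types = FALSE)
  e$rms[3] <- NA
  readr::write_csv(e, file.path(dir, "excerpts.csv"))
  expect_error(read_dataset(dir), class = "vacommittee_io_error")
})
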