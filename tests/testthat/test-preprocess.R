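test_that("correlation matrix matches a direct covariance/sigma oracle", {
  set.seed(42)
  tab <- tibble::as_tibble(matrix(rnorm(50), 10, 5,
                                  dimnames = list(NULL, paste0("f", 1:5))))
  rep <- correlation_matrix(tab)
  oracle <- function(x, y) {
    mean((x - mean(x)) * (y - mean(y))) /
      (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
  }
  for (i in 1:5) {
    for (j in 1:5) {
      expect_equal(rep$r[i, j], oracle(tab[[i]], tab[[j]]), tolerance = 1e-12)
    }
  }
  expect_equal(diag(rep$r), setNames(rep(1, 5), paste0("f", 1:5)))
  expect_equal(rep$r, t(rep$r))
})

test_that("exactly linear columns give r of +1 and -1", {
  tab <- tibble::tibble(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
  rep <- correlation_matrix(tab)
  expect_equal(rep$r["a", "b"], 1, tolerance = 1e-12)
  expect_equal(rep$r["a", "c"], -1, tolerance = 1e-12)
})

test_that("zero-variance columns are flagged and never count as violations", {
  tab <- tibble::tibble(a = rnorm(10), b = rnorm(10), k = rep(2, 10))
  rep <- correlation_matrix(tab)
  expect_equal(rep$zero_variance, "k")
  red <- reduce_features(rep, 0.8)
  expect_true("k" %in% red$retained)
})

test_that("greedy reduction on the spectral pattern removes centroid then rolloff", {
  red <- reduce_features(example_audio_correlations(), 0.8)
  expect_equal(red$removed, c("centroid", "rolloff"))
  expect_true(all(c("spread", "brightness") %in% red$retained))
  expect_equal(red$trace$feature, c("centroid", "rolloff"))
  expect_equal(red$trace$n_violations[1], 3L)
})

test_that("the physiological pattern keeps all five features", {
  red <- reduce_features(example_physio_correlations(), 0.8)
  expect_length(red$removed, 0)
  expect_setequal(red$retained, physio_feature_names())
})

test_that("after reduction no surviving pair violates the threshold, and reduction is idempotent", {
  set.seed(7)
  for (i in 1:100) {
    n_feat <- sample(4:8, 1)
    base <- matrix(rnorm(12 * 3), 12, 3)
    load <- matrix(rnorm(3 * n_feat), 3, n_feat)
    x <- base %*% load + matrix(rnorm(12 * n_feat, sd = 0.4), 12, n_feat)
    colnames(x) <- paste0("f", seq_len(n_feat))
    rep <- correlation_matrix(tibble::as_tibble(x))
    red <- reduce_features(rep, 0.8)
    sub <- abs(rep$r[red$retained, red$retained, drop = FALSE])
    diag(sub) <- 0
    expect_true(all(sub <= 0.8))
    rep2 <- as_correlation_report(rep$r[red$retained, red$retained, drop = FALSE])
    expect_length(reduce_features(rep2, 0.8)$removed, 0)
  }
})

test_that("removal trace is unchanged by row permutation of the input table", {
  e <- default_study$excerpts
  set.seed(1)
  shuffled <- e[sample(nrow(e)), ]
  t1 <- reduce_features(correlation_matrix(e, audio_feature_names()))$trace
  t2 <- reduce_features(correlation_matrix(shuffled, audio_feature_names()))$trace
  expect_equal(t1$feature, t2$feature)
  expect_equal(t1$n_violations, t2$n_violations)
})

test_that("min-max scaling maps the observed range onto [0, 1]", {
  tab <- tibble::tibble(x = c(2, 4, 6))
  params <- fit_minmax(tab)
  expect_equal(apply_minmax(params, tab)$x, c(0, 0.5, 1))
  # new data outside the fitted range is not clipped
  expect_equal(apply_minmax(params, tibble::tibble(x = c(0, 8)))$x, c(-0.5, 1.5))
})

test_that("constant features warn and map to 0.5", {
  tab <- tibble::tibble(x = rep(3, 4))
  expect_warning(params <- fit_minmax(tab), "Constant")
  expect_equal(apply_minmax(params, tab)$x, rep(0.5, 4))
})

test_that("rating rescaling is the documented affine map and inverts exactly", {
  expect_equal(rescale_rating(c(-1, 0, 1)), c(0, 0.5, 1))
  expect_equal(rescale_rating(0.5), 0.75)
  v <- seq(-1, 1, length.out = 101)
  expect_equal(unrescale_rating(rescale_rating(v)), v, tolerance = 1e-12)
})

test_that("baseline subtraction is exact and refuses missing values", {
  expect_equal(baseline_subtract(5.2, 3.1), 2.1)
  expect_equal(baseline_subtract(4, 4), 0)
  x <- rnorm(20)
  b <- rnorm(20)
  expect_equal(baseline_subtract(x, b), x - b, tolerance = 1e-15)
  expect_error(baseline_subtract(c(1, NA), c(1, 1)),
               class = "vacommittee_input_error")
  expect_error(baseline_subtract(1, NA), class = "vacommittee_input_error")
})

test_that("feature-rating correlations report df = n - 2 and exact r", {
  fc <- feature_rating_correlations(default_study$excerpts)
  expect_equal(unique(fc$df), 58)
  expect_equal(nrow(fc), 17 * 2)
  ed <- fc[fc$feature == "eventdensity" & fc$dimension == "arousal", ]
  expect_equal(ed$r, cor(default_study$excerpts$eventdensity,
                         default_study$excerpts$arousal_mean),
               tolerance = 1e-12)
})

test_that("a perfectly linear feature has r = 1 and p near zero", {
  tab <- tibble::tibble(f = 1:10, valence_mean = (1:10) / 10 - 0.5,
                        arousal_mean = rnorm(10))
  fc <- feature_rating_correlations(tab, features = "f")
  expect_equal(fc$r[fc$dimension == "valence"], 1, tolerance = 1e-9)
  expect_lt(fc$p[fc$dimension == "valence"], 1e-12)
})

test_that("t-distribution p values agree with a permutation oracle", {
  set.seed(202)
  tab <- tibble::tibble(f = rnorm(10),
                        valence_mean = rnorm(10) * 0.3,
                        arousal_mean = rnorm(10) * 0.3)
  fc <- feature_rating_correlations(tab, features = "f")
  r_obs <- fc$r[fc$dimension == "valence"]
  p_t <- fc$p[fc$dimension == "valence"]
  perm <- replicate(1e4, abs(cor(sample(tab$f), tab$valence_mean)))
  p_perm <- mean(perm >= abs(r_obs))
  expect_lt(abs(p_t - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 1e4) + 0.02)
})

test_that("preprocess_study assembles scaled features and 0-1 targets", {
  prep <- preprocess_study(default_study)
  expect_true(all(prep$excerpts$valence01 >= 0 & prep$excerpts$valence01 <= 1))
  for (f in c(prep$audio_features, prep$physio_features)) {
    expect_equal(range(prep$excerpts[[f]]), c(0, 1))
  }
  expect_setequal(prep$physio_features, physio_feature_names())
  expect_equal(rescale_rating(default_study$excerpts$valence_mean),
               prep$excerpts$valence01)
})
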