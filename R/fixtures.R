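#' Example audio correlation pattern
#'
#' A 12-feature correlation matrix reproducing the reduction scenario the
#' pipeline is built around: `centroid` is strongly correlated (|r| > 0.8)
#' with all three other spectral features, `spread` and `rolloff` are
#' strongly correlated with two (each other and `centroid`), and
#' `brightness` only with `centroid`; `rolloff` additionally carries a
#' moderate correlation with `rms`. Greedy reduction at threshold 0.8
#' removes `centroid` first (three violations) and then `rolloff`
#' (tie with `spread` broken by its larger mean |r| to the remaining
#' features), retaining `spread` and `brightness`.
#'
#' @param n Nominal sample size recorded in the report.
#' @return A `correlation_report`.
#' @export
#' @examples
#' reduce_features(example_audio_correlations())$removed
example_audio_correlations <- function(n = 60L) {
  feats <- audio_feature_names()
  r <- diag(length(feats))
  dimnames(r) <- list(feats, feats)
  set_r <- function(m, a, b, v) {
    m[a, b] <- v; m[b, a] <- v; m
  }
  r <- set_r(r, "centroid", "spread", 0.86)
  r <- set_r(r, "centroid", "rolloff", 0.82)
  r <- set_r(r, "centroid", "brightness", 0.82)
  r <- set_r(r, "spread", "rolloff", 0.87)
  r <- set_r(r, "spread", "brightness", 0.57)
  r <- set_r(r, "rolloff", "brightness", 0.52)
  r <- set_r(r, "rolloff", "rms", 0.30)
  # mild background structure among the remaining features
  r <- set_r(r, "rms", "lowenergy", -0.35)
  r <- set_r(r, "eventdensity", "tempo", 0.40)
  r <- set_r(r, "brightness", "irregularity", 0.25)
  as_correlation_report(r, n = n)
}

#' Example physiological correlation pattern
#'
#' A 5-feature correlation matrix in which no pair exceeds |r| = 0.8, so
#' correlation-threshold reduction retains all five features.
#'
#' @param n Nominal sample size recorded in the report.
#' @return A `correlation_report`.
#' @export
example_physio_correlations <- function(n = 60L) {
  feats <- physio_feature_names()
  r <- diag(length(feats))
  dimnames(r) <- list(feats, feats)
  set_r <- function(m, a, b, v) {
    m[a, b] <- v; m[b, a] <- v; m
  }
  r <- set_r(r, "HR", "SCL", 0.55)
  r <- set_r(r, "HR", "Resp", 0.45)
  r <- set_r(r, "Resp", "SCL", 0.40)
  r <- set_r(r, "Zyg", "Corr", -0.65)
  r <- set_r(r, "Zyg", "SCL", 0.20)
  as_correlation_report(r, n = n)
}
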