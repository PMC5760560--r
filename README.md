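# vacommittee

Committee-machine modeling of music emotion judgments in R.

When people judge the emotion of a piece of music, two sources of evidence
are in play: what they *perceive* in the sound itself (the cognitivist
position) and what they *feel* in their own body while listening (the
emotivist position). `vacommittee` implements a hybrid computational account
of this judgment: one ensemble of small neural networks predicts valence and
arousal from audio features of the music (the **perception** expert), a
second ensemble predicts them from listener psychophysiology — heart rate,
respiration, skin conductance, zygomaticus and corrugator EMG (the
**feeling** expert) — and a meta-level **committee machine** combines the two
experts and quantifies how much each contributes to the final judgment.

The package is aimed at researchers in music cognition and affective
computing who want a fully reproducible, end-to-end version of this
modeling strategy, including a synthetic-data generator that emulates the
underlying listening-study design, so the entire analysis runs from a single
seed with no external data.

## The model

Emotion ratings are collected on valence and arousal scales in [-1, 1] and
rescaled to [0, 1] for modeling. For each emotion dimension *d* and feature
set (audio or physiology):

* **Experts.** Five feedforward networks (inputs → 3 sigmoid hidden units →
  1 sigmoid output) are trained under genre-stratified five-fold
  cross-validation. Weights initialize uniformly in (-0.05, 0.05) and are
  updated by batch backpropagation — per-example squared-error gradients are
  summed over the epoch and applied in one update with learning rate 0.1 —
  until the training mean squared error falls below 0.045. The ensemble
  prediction is the unweighted mean of the five fold-networks' outputs.
* **CMEA** (committee machine, ensemble-averaged): combines the perception
  output x₁ and feeling output x₂ with equal weights,
  y = 0.5·x₁ + 0.5·x₂.
* **CMLR** (committee machine, linear regression): fits
  y_d = b₁·x₁ + b₂·x₂ + c by ordinary least squares and reports each
  expert's **contribution percentage**, 100·|b₁|/(|b₁|+|b₂|) and its
  complement, ignoring the intercept.
* **Comparison arms.** Per-fold stepwise forward regression (p-of-F to
  enter ≤ 0.05, to remove ≥ 0.10; folds may yield "no model") averaged as an
  ensemble, and a bagged random-forest regressor trained once on the 44
  training excerpts.

Before modeling, features pass a correlation filter: while any pair of
features has |r| > 0.8, the feature with the most strongly-correlated
partners is removed (ties broken by larger mean |r|). Retained features are
min–max scaled to [0, 1].

The data layout mirrors the listening study being emulated: 60 excerpts in
4 genres; 16 excerpts (4 per genre) held out for testing; 4 excerpts (1 per
genre) included in every training set; the remaining 40 split into five
genre-balanced folds of 8, so each fold-network trains on 36 excerpts.

## Worked example

```r
library(vacommittee)

res <- run_pipeline(pipeline_config(seed = 1))
res$report
#>    method              dimension feature_set   rmse n_models no_model perc_pct feel_pct
#>  1 neural network      valence   audio        0.217        5 FALSE        NA       NA
#>  2 neural network      valence   physio       0.258        5 FALSE        NA       NA
#>  3 neural network      arousal   audio        0.229        5 FALSE        NA       NA
#>  4 neural network      arousal   physio       0.229        5 FALSE        NA       NA
#>  5 stepwise regression valence   audio        0.155        5 FALSE        NA       NA
#>  6 stepwise regression valence   physio       0.224        2 FALSE        NA       NA
#>  7 stepwise regression arousal   audio        0.212        5 FALSE        NA       NA
#>  8 stepwise regression arousal   physio       0.198        5 FALSE        NA       NA
#>  9 random forest       valence   audio        0.192        1 FALSE        NA       NA
#> 10 random forest       valence   physio       0.246        1 FALSE        NA       NA
#> 11 random forest       arousal   audio        0.214        1 FALSE        NA       NA
#> 12 random forest       arousal   physio      0.183         1 FALSE        NA       NA
#> 13 CMEA                valence   audio+physio 0.233       NA FALSE        NA       NA
#> 14 CMLR                valence   audio+physio 0.163       NA FALSE        92.1      7.9
#> 15 CMEA                arousal   audio+physio 0.229       NA FALSE        NA       NA
#> 16 CMLR                arousal   audio+physio 0.154       NA FALSE        43.2     56.8
```

Each row is one modeling arm's root mean-squared error on the 16 held-out
test excerpts (0–1 rating scale; smaller is better). `n_models` counts the
fold models contributing to the ensemble — stepwise folds that produce no
significant model are dropped, and a cell where *no* fold produces one
renders as `"no model"`. The CMLR rows carry the contribution percentages;
with this seed's synthetic data (valence generated mostly from the audio
channel, arousal mostly from physiology), the committee recovers the
expected asymmetry: valence judgments are dominated by the perception
expert (92.1%), arousal judgments by the feeling expert (56.8%).

```r
print(res$committees$arousal$cmlr)
#> <committee_model> arousal: y = 253.849*x_perc + 334.001*x_feel + -294.117 (n = 60)
#>   contributions: perception 43.2% | feeling 56.8%

tidy(res$committees$arousal$cmlr)
#> # A tibble: 3 × 3
#>   term       estimate contribution_pct
#> 1 perception     254.             43.2
#> 2 feeling        334.             56.8
#> 3 intercept     -294.             NA
```

Fitted objects follow broom conventions (`tidy()`, `glance()`) and result
objects have `autoplot()` methods (correlation heatmap, training trace,
results grid). `run_pipeline(..., out_dir = "run")` additionally writes
every stage artifact (`excerpts.csv`, `ratings.csv`, `partition.json`,
per-network weight files, `committee.json`, `report.csv/json`, run log).

The published stacking coefficients can be fed straight into the
contribution computation:

```r
contributions(c(0.757, 0.164))  # valence -> 82.2% perception / 17.8% feeling
contributions(c(0.813, 0.968))  # arousal -> 45.6% perception / 54.4% feeling
```

## Scope

The package ingests or simulates already-extracted, per-excerpt feature
tables. Audio feature extraction from recordings, physiological signal
acquisition/filtering, and continuous (bar-by-bar) rating collection are
out of scope; see the methods vignette (`vignettes/committee-machines.Rmd`)
for the generator's assumptions and the package's design decisions.
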