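---
title: "Committee machines for music emotion judgments: models, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Committee machines for music emotion judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vacommittee)
```

## The modeling problem

A listener's judgment of the emotion in a music excerpt is summarized by
two continuous dimensions: valence (unpleasant to pleasant) and arousal
(calm to excited), each rated on $[-1, 1]$ and averaged over the listeners
who heard that excerpt. The package models these mean judgments from two
separate evidence channels:

* a **perception** channel — features of the audio itself (dynamics,
  rhythm, timbre, tonality: `rms`, `lowenergy`, `eventdensity`, `tempo`,
  `pulseclarity`, `centroid`, `spread`, `rolloff`, `brightness`,
  `irregularity`, `inharmonicity`, `mode`);
* a **feeling** channel — baseline-corrected physiological features of the
  listener (`HR`, `Resp`, `SCL`, `Zyg`, `Corr`), where zygomaticus and
  corrugator EMG track valence and the autonomic measures track arousal.

The hybrid hypothesis is that the judgment is a meta-level combination of
the two channels. The package operationalizes it as a two-layer model:
channel-specific expert ensembles (small multilayer perceptrons), and a
committee machine that combines the experts' outputs.

## Experts: MLP ensembles under stratified cross-validation

Each expert network is a feedforward perceptron with one hidden layer of 3
sigmoid units and a sigmoid output, so predictions live in $(0, 1)$ and
targets are affinely rescaled from $[-1, 1]$ to $[0, 1]$ via
$v' = (v + 1)/2$. Inputs are min–max scaled to $[0, 1]$ per feature.
Training is plain batch gradient descent: weights initialize uniformly in
$(-0.05, 0.05)$; each epoch presents all training examples in a fresh
random order, accumulates per-example squared-error gradients, and applies
a single summed update with learning rate $0.1$; training stops when the
epoch's training mean squared error drops below $0.045$. There is no
momentum, weight decay, adaptive step size, early stopping on validation
data, or minibatching — the training loop is deliberately minimal so that
every arithmetic step is inspectable and testable against a
finite-difference oracle.

The data layout is bespoke: of 60 excerpts (15 per genre in 4 genres), 16
(4 per genre) are held out for testing; 4 (1 per genre) join every training
set but are never validated against; the remaining 40 form five
genre-balanced folds of 8 (2 per genre). Each fold's network trains on the
other four folds plus the always-train excerpts — 36 excerpts, 9 per genre
— and the five networks are used together as an unweighted-average
ensemble. Separate networks are trained per emotion dimension, so a
valence network never sees arousal targets.

### Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `learning_rate` | 0.1 | step size on summed gradients | the study's stated value; stable for 36-example batches |
| `target_mse` | 0.045 | squared error on the 0–1 scale | the study's stated stopping threshold |
| `max_epochs` | 50000 | epochs | safety cap; physiology networks converge slowest |
| `init_half_range` | 0.05 | weight units | the stated uniform initialization bound |
| `use_bias` | `TRUE` | logical | see *Open design decisions* |
| `n_hidden` | 3 | units | the study's architecture |

## The committee machines

Let $x_1$ and $x_2$ be the perception- and feeling-ensemble outputs for an
excerpt (0–1 scale).

* **CMEA** combines them with fixed equal weights:
  $y = 0.5\,x_1 + 0.5\,x_2$.
* **CMLR** fits $y_d = b_1 x_1 + b_2 x_2 + c$ by ordinary least squares on
  the per-excerpt ensemble outputs and mean ratings, separately per
  dimension. The **contribution percentages** are
  $100\,|b_1| / (|b_1| + |b_2|)$ for perception and the complement for
  feeling, ignoring the intercept. Magnitudes are used so the split is
  invariant to rescaling both coefficients and well-defined under sign
  flips, which can occur on synthetic data; for positive coefficients the
  magnitudes change nothing. Reported percentages are rounded half-up to
  one decimal.

Because the stacking is ordinary least squares over a family that contains
the equal-weight combination, CMLR's in-sample RMSE can never exceed
CMEA's on the fitting set; the pipeline asserts this invariant on every
run.

Two points deserve honesty. First, the committee regression is fit on all
60 excerpts, including the 16 test excerpts — this mirrors the procedure
being reproduced and is the default, but it leaks test information into
the committee weights; `pipeline_config(committee_scope = "train")`
restricts fitting to the 44 training excerpts for a leakage-free variant.
Second, because each expert stops training as soon as its MSE crosses the
fairly loose 0.045 threshold, ensemble outputs can have small spread, and
the stacking coefficients then compensate in scale (they can be far from
1). The contribution percentages remain meaningful because they are
scale-invariant in the joint rescaling sense above, but they should be read
as contributions of the *standardized* expert signals, with the coefficient
scale absorbing each ensemble's output spread.

## Comparison arms

**Stepwise forward regression** runs once per cross-validation fold on that
fold's 36 training excerpts: at each step the candidate with the smallest
partial-F p-value enters if $p \le$ `p_enter` (0.05), and after each entry
any included variable with $p \ge$ `p_remove` (0.10) is removed;
`p_enter < p_remove` is enforced to prevent cycling. A fold where nothing
enters yields a "no model" outcome; the ensemble averages only the folds
that produced models and reports how many did. An all-"no model" cell
propagates as such in the results grid — it is an expected outcome, not an
error.

**Random forests** (one per dimension and feature set) are trained once on
the 44 training excerpts with 500 trees, `floor(p/3)` features per split
and a minimum node size of 5 — conventional regression-forest practice, as
the original hyperparameters are unstated. Bagging already controls
overfitting, so no cross-validation is used for this arm. The forest
implementation is the established `randomForest` package behind the
package's `fit_forest()`/`forest_predict()` contract; the networks,
committees, feature reduction, generator and partition logic are authored
in this package.

All arms consume the same scaled features and 0–1 targets and are
evaluated by RMSE on the same 16 test excerpts, collected in a single
results grid.

## Feature reduction and preprocessing

The audio features include a block of four spectral descriptors
(`centroid`, `spread`, `rolloff`, `brightness`) that are strongly
inter-correlated. Reduction is a greedy loop on the Pearson correlation
matrix: while any surviving pair has $|r|$ strictly above 0.8, remove the
feature with the most violating partners, breaking ties by the larger mean
$|r|$ to the remaining features and then by input order. This rule
reproduces the canonical outcome on the documented spectral pattern
(`example_audio_correlations()`): `centroid` falls first with three
violations, then `rolloff`, leaving `spread` and `brightness`. The same
threshold applied to the five physiological features removes nothing.
Zero-variance columns have undefined correlations; they are flagged and
never counted as violations. Reduction is idempotent by construction and
its trace is invariant to row order of the input table.

Min–max bounds are fit at dataset level (all 60 excerpts) before
partitioning, matching the described dataset-level scaling step; this too
leaks test-set range information, and `scaling_scope = "train"` fits the
bounds on training excerpts only (applied values are then not clipped and
may fall outside $[0, 1]$ for test data — deliberate, since clipping would
distort the affine contract).

Physiological features arrive baseline-corrected: the generator emits the
corrected values together with the white-noise baseline levels, and
`baseline_subtract()` implements the correction for ingested raw data,
erroring on missing baselines rather than treating them as zero. The
pipeline subtracts before scaling (subtract-then-scale); the opposite
order would conflate baseline level with excerpt response in the min–max
bounds.

## What the synthetic generator emulates — and what it does not

No dataset was deposited with the study this design emulates, so the
generator is a first-class, tested module that reproduces the *statistical
and design structure* the pipeline needs:

* **Design:** 60 excerpts, 4 genres × 15; 60 participants each rating 12
  excerpts (3 per genre); every excerpt rated by exactly 12 participants.
  The incidence is a per-genre cyclic block design with seeded relabeling,
  balanced for every seed (property-tested over 20 seeds); infeasible
  configurations raise an explicit error.
* **Collinear spectral block:** the four spectral features share one latent
  factor plus independent jitter calibrated so every pairwise population
  correlation equals `collinear_r` (default 0.9). Note the single-factor
  construction makes *all six* block pairs collinear, so default-condition
  runs retain 9 audio features; the partially-collinear pattern in which
  exactly `centroid` and `rolloff` fall is exercised through the
  `example_audio_correlations()` fixture.
* **Physiological couplings:** `Zyg` loads positively and `Corr` negatively
  on a latent valence state; `HR`, `Resp`, `SCL` load positively on a
  latent arousal state, with loadings (0.65–0.85) chosen to keep all
  pairwise physiological correlations below the 0.8 reduction threshold.
* **Latent emotion:** $v = w_{perc}\,g(\text{audio}) +
  w_{feel}\,h(\text{physio})$, where $g$ and $h$ are fixed degree-2
  polynomials squashed by $\tanh$ (coefficients hard-coded in
  `R/generator.R`); the mixture is convex so latents stay in $[-1, 1]$.
  Smooth, bounded, learnable by a 3-hidden-unit sigmoid network — and with
  $w = (1, 0)$ the latent is *exactly* a function of one channel, which is
  what makes ordinal contribution recovery testable.
* **Mixing defaults** are valence $(0.8, 0.2)$ and arousal
  $(0.45, 0.55)$: the study conditions being emulated, namely
  perception-dominant valence and mildly feeling-dominant arousal. They
  were fixed once, from the reported contribution pattern, not adjusted
  afterwards.
* **Ratings:** per-participant rating = latent + Gaussian noise
  (`rating_noise_sd`, default 0.3 on the $[-1,1]$ scale — a free choice,
  as no per-rater noise magnitude is reported), clipped to $[-1, 1]$ like
  a bounded rating grid; excerpt means average the 12 raters, shrinking
  rating error by about $\sqrt{12}$ (verified by simulation in the tests).

What it deliberately does **not** emulate: continuous bar-by-bar rating
trajectories (only excerpt-level summaries exist here); raw physiological
waveforms and their filtering; genre structure beyond modest mean shifts
in rhythm/dynamics features; familiarity or preference effects;
non-Gaussian rater idiosyncrasies (per-rater bias, scale use). Passing
tests therefore demonstrate that the *pipeline machinery* — reduction,
partitioning, training, stacking, reporting — behaves correctly and that
the committee recovers the generative channel asymmetry; they do not
certify performance numbers on real listening data, whose headline RMSEs
depend on the undeposited original dataset and are not reproducible.

## Numerical choices

* Training loss for gradients is the summed squared error
  $L = \sum_i (y_i - t_i)^2$; the stopping statistic is its mean over the
  36 training examples, on the 0–1 scale (the natural scale of the sigmoid
  output). The epoch MSE is computed from the forward passes of that epoch,
  i.e. before the end-of-epoch update.
* Analytic gradients are validated against central finite differences
  ($\varepsilon = 10^{-6}$) to a per-component relative error below
  $10^{-5}$ on 100+ random small networks.
* The batch update is a sum over examples, hence invariant to presentation
  order up to floating-point association (tested at $10^{-10}$); the
  per-epoch shuffling is retained as part of the documented procedure.
* Non-convergence at `max_epochs` is a warning, not an error, and the best
  weights seen are retained — with noisy targets, a network whose best
  achievable MSE sits just above 0.045 is still a usable ensemble member.
* A non-finite gradient aborts training with a diagnostic.
* Constant features scale to 0.5 with a warning; degenerate correlations
  are flagged rather than silently zeroed; collinear committee predictors
  raise an error naming the problem.
* All randomness flows from one master seed through named substreams
  (design, audio, physio, ratings, partition, one per network, one per
  forest), so any stage can be reproduced in isolation and two runs at one
  seed produce byte-identical reports.

## Open design decisions

* **Bias units** are not part of the documented weight list ($W_{hi}$,
  $W_{oh}$ only); the default includes them because they materially help
  a 3-unit network fit targets whose mean is far from 0.5, and
  `use_bias = FALSE` gives the strict minimal variant.
* **Always-train selection**: how the 4 excerpts excluded from
  cross-validation were chosen is unstated; here they are drawn uniformly
  within genre strata from the seed, like the test set and folds.
* **Stepwise criteria**: the conventional p-of-F scheme
  (enter $\le 0.05$, remove $\ge 0.10$) is used, with both thresholds
  configurable; stepwise runs on each fold's 36-excerpt training set,
  mirroring the network folds, so fold-dependent "no model" outcomes are
  expected behavior.
* **Committee input scale**: ensemble outputs enter the committee on the
  0–1 scale, consistent with intercepts of the size reported for the
  stacking equations.
* The printed stacking coefficient pair used in the worked examples is
  $(0.757, 0.164)$ for valence; these values reproduce the published
  82.2%/17.8% split exactly, which is the consistency check the
  contribution operation is tested against.

## Problem sizes and runtime

The default conditions (60 excerpts, 20 networks, 500-tree forests) run the
full pipeline in a few seconds on one core; the test suite, including two
full pipeline runs, 100-network gradient checks and the Monte-Carlo rating
simulations, completes in about a minute. These sizes are the study
conditions themselves, so nothing is scaled down.

## Known limitations

* Contribution percentages compare coefficient magnitudes, not variance
  explained; when the two ensembles' output spreads differ strongly the
  percentages conflate signal salience with output scale (inherited from
  the method being reproduced).
* Fitting CMLR and the min–max bounds on all 60 excerpts leaks test
  information; both have leakage-free switches, which change the numbers.
* With 16 test excerpts, test RMSEs have substantial sampling variance;
  differences of a few hundredths between arms are not meaningful.
* The generator's single-factor spectral block is more collinear than real
  spectral descriptors, which show a partial violation pattern; reduction
  outcomes on real data will differ accordingly.
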