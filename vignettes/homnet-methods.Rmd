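---
title: "Moment-based high-order functional connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-based high-order functional connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homnet)
```

## The pipeline and its assumptions

`homnet` implements a four-stage analysis of ROI time series: dynamic
connectivity, central-moment feature networks, high-order networks, and
classification with ensemble voting. The input is one matrix per subject
(M time points × R regions, e.g. 170 × 116 for a standard acquisition with
the AAL parcellation) that is assumed to be fully preprocessed — detrended,
nuisance-regressed, band-passed and parcellated. The package deliberately
starts *after* preprocessing: its subject matter is the network construction
and evaluation, not image processing.

### Dynamic connectivity (LoD-FCN)

A window of length `W` slid with step `s` yields
K = ⌊(M − W)/s⌋ + 1 segments; each segment's region-by-region Pearson
correlation matrix is one "subnetwork" of the low-order dynamic FC network.
The floor convention drops a trailing partial window: a shorter final
segment would estimate correlation at a different (lower) precision than the
others, silently mixing two estimators. With the canonical settings
(M = 170, W = 30, s = 2) the division is exact and K = 71.

Pearson's sample correlation is used throughout, with one guard: a region
that is constant within a segment has no defined correlation, and such
entries are set to 0 with a warning rather than propagating NaN. Zero is the
unique value that is neutral for the downstream moment features and keeps
every matrix finite; the warning preserves detectability. No Fisher
z-transform is applied anywhere — all downstream statistics operate on raw
correlations in [−1, 1].

### Central-moment networks CM(d)

Each edge's windowed correlation series is summarized by the order-d
central-moment feature: the signed d-th root of the 1/K-averaged centered
power sum. Three numerical choices matter:

* **Signed root.** For odd d the averaged power sum can be negative; the
  root is applied as sign(S)·|S|^(1/d), which keeps the feature real and
  preserves the direction of skew. (Absolute-value roots would discard
  exactly the asymmetry information that odd orders exist to carry.)
* **Population normalization (1/K).** The moment divides by K, not K − 1;
  the feature is a descriptive summary of the realized window series, not an
  unbiased estimator of a population moment.
* **Order-insensitive summation.** The K values are sorted before any
  accumulation. Floating-point addition is not associative, so summing in
  window order would make CM(d) depend — in the last bits — on the window
  order it is meant to be invariant to. After sorting, permuting the windows
  of the dynamic network leaves CM(d) and everything downstream *bitwise*
  unchanged, and the test suite asserts this with `identical()` rather than
  a tolerance.

At d = 1 the centered sum is identically zero, so the mean of the series is
substituted. Consequently CM(1) has unit diagonal (the self-series is
constantly 1) and CM(d ≥ 2) has an exactly zero diagonal; both are asserted
on every build. The RMS network (per-edge root mean square of the windowed
series) is provided as the conventional comparison feature.

### High-order networks Ho(d)

Row i of CM(d) is region i's moment profile; Ho(d) is the Pearson
correlation between every pair of profiles. By default the full row
participates, including the degenerate diagonal entry — this matches the
definition of the row profile as all R entries. Because the d ≥ 2 diagonal
is a shared constant 0, its inclusion slightly inflates positive
correlations; `build_hofcn(include_diagonal = FALSE)` removes both self
entries of each pair instead, and both paths are tested. A constant profile
(zero variance) correlates as 0 with a warning, mirroring the connectivity
convention.

## Classification

Features are the strict lower triangle of a network, vectorized column-major
— R(R−1)/2 values under a fixed edge ordering ((2,1), (3,1), …) reused across
all subjects and networks, so a feature index always denotes the same region
pair. (For a symmetric matrix this is the only dimensionality consistent
with "off-diagonal triangle"; 6670 features at R = 116.)

Selection and learning are nested to avoid optimistic bias:

* **Outer loop**: `repetitions` independent stratified 5-fold partitions;
  each outer test fold is predicted exactly once per repetition.
* **Inner loop**: on the training folds only, a stratified 5-fold grid
  search chooses the t-test threshold p ∈ {0.01, 0.05, 0.1}, the LASSO
  penalty, and the SVM cost C ∈ {0.1, 1, 10} by mean inner accuracy.

The two-sample t-test is the classic pooled-variance Student test (two
classes assumed to share a variance per feature), vectorized over features;
zero-variance features are excluded with a warning, and the implementation
is cross-checked against `stats::t.test(var.equal = TRUE)` in the tests.

The LASSO objective is ½‖I − Ŷω‖² + λ‖ω‖₁ with no intercept, solved by
`glmnet` with the penalty mapped onto glmnet's 1/(2n)-scaled objective
(λ_glmnet = λ/n, `standardize = FALSE`, `intercept = FALSE`); an independent
cyclic coordinate-descent oracle verifies the coefficients in the test
suite. Features are z-scored with training-fold statistics before the LASSO
and SVM — L1 penalties are scale-sensitive, and per-fold standardization
keeps the test fold untouched. λ is tuned as a *ratio* of
λ_max = max|XᵀI| computed on each local standardized, t-filtered design
(10-point log grid from 0.01·λ_max to λ_max): the ratio is comparable
across folds even though the absolute λ_max varies with the surviving
feature set. Ties in the inner search are broken toward larger λ, then
smaller C, then smaller p-threshold — the most parsimonious of the tied
models.

When the tuned pipeline selects no feature at all (common under a null
cohort, where the honest answer is "nothing discriminates"), the fold falls
back to predicting the training-fold majority label, and the fold record
flags it. All randomness derives from the master seed, so a `nested_cv`
call is exactly reproducible; per-repetition seeds are drawn once from the
master stream.

Metrics are ACC, TPR (sensitivity), TNR (specificity) and F1, each computed
per outer fold from the fold's confusion counts and averaged over all folds
of all repetitions; a metric with a zero denominator in some fold is NA for
that fold (with a warning) rather than a fabricated 0. Selection frequency
is the fraction of outer folds in which a feature survives both selection
steps — 49 selections out of 10 × 5 folds give 0.98.

## Majority voting

Per-network classifiers evaluated under the *same* fold partitions (same
cohort, seed, repetitions — enforced, since out-of-fold predictions must
align subject-by-subject) are combined by majority vote: a label wins when
it receives strictly more than half of the T votes. With an even panel a tie
is possible; formally the vote is rejected, and the package resolves it to
the vote of the member with the highest aggregate accuracy. All standard
strategies (`standard_strategies()`) use odd T, where rejection is provably
impossible — the test suite asserts this property. Ensemble metrics use the
same fold-level aggregation as the members, so a one-member "ensemble"
reproduces that member's metrics exactly.

## The synthetic cohort generator

The generator exists so that every stage — including effect recovery by the
full nested-CV pipeline — can be exercised with no imaging data. It encodes
the hypothesis the framework targets: groups that differ not in mean
coupling but in the *moments* of coupling dynamics.

Each subject's signal is blockwise multivariate Gaussian: within a block of
`block_length` time points the target correlation matrix is constant; from
block to block, the correlation of each *affected edge* is perturbed around
the base coupling by volatility·z (z standard normal, with an optional skew
term), clipped to ±0.95, and the perturbed matrix is repaired to the nearest
valid correlation matrix by eigenvalue flooring before sampling. White
observation noise is added last. Blocks map one-to-one onto analysis windows
of the same length, so the injected block-to-block variance appears directly
as window-to-window FC variance — effect sizes are controllable by
construction.

Defaults (chosen once as the package's reference conditions): R = 20
regions, M = 120 time points, block length 30, base coupling 0.2, 30
subjects per group, volatility 0.3 in the affected group versus 0.05 in
controls on 10 affected edges, observation noise SD 0.25. The affected
edges default to a *disjoint matching* (2,1), (4,3), …, (20,19). The layout
matters: if all affected edges share one hub region, the group effect
approximately rescales a single row of CM(2), and Ho(d) — being a
correlation — is invariant to row scaling, so a hub effect is structurally
invisible at the high-order level. A matching perturbs each affected
region's profile at a distinct position, changing profile *shape*, which is
what the high-order stage detects.

What the generator does **not** emulate: hemodynamic convolution and
autocorrelation of BOLD noise, non-Gaussian signal, motion and scanner
artifacts, site effects, or realistic anatomical covariance structure. The
pipeline consumes only second-order structure, so Gaussian blocks are
sufficient to validate the *mechanics* (and the null calibration), but
passing tests on synthetic cohorts say nothing about classification
accuracy on real cohorts — real-data accuracies depend on the cohort and
cannot be reproduced from simulation.

## Problem sizes and determinism in the shipped tests

The test suite and the acceptance script use deliberately small instances:
oracle comparisons at R ≤ 6, M ≤ 50 against naive brute-force
implementations (tolerance 1e−12); fuzzing of structural invariants over
100 random inputs; null calibration with 20 + 20 subjects and effect
recovery with 30 + 30 subjects at R = 20, M = 120, W = 30, s = 2, three
CV repetitions. These sizes give stable Monte-Carlo behaviour (the null
band is the 99% binomial interval around chance on the total number of
out-of-fold predictions) while keeping a full run in tens of seconds.
Stochastic checks fix their seeds; exact checks (window counts, worked
selection-frequency example, metric arithmetic, permutation invariance)
hold to the bit or to printed precision.

## Known limitations

* Windowed Pearson correlation only: no tapered windows, wavelet or
  phase-based dynamic FC, and no HMM-style state models.
* Binary classification with a linear SVM; no multi-class support,
  nonlinear kernels, elastic net, or probability calibration.
* Classifier-level fusion only; feature-level fusion across networks is out
  of scope.
* The on-disk network format (delimited text with a `#` metadata header) is
  a package convention chosen for diff-ability, not an interchange standard.
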