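---
title: "Connectome embedding and predictive modeling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome embedding and predictive modeling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`neurocpm` implements connectome-based predictive modeling (CPM) of behavioral
phenotypes from resting-state fMRI parcel timeseries, with per-parcel node
embeddings of the functional connectome as the primary feature representation.
The pipeline runs in five stages:

1. **Connectivity.** Parcel timeseries are censored by framewise displacement
   (FD), detrended and demeaned on low-motion frames, residualized against
   nuisance confounds, interpolated over censored frames, bandpass filtered
   with a zero-phase Butterworth filter, and correlated (Pearson) over
   retained frames only.
2. **Embedding.** Each subject's connectivity matrix becomes a weighted graph;
   biased random walks over that graph form a corpus and skip-gram training
   with negative sampling assigns each parcel a latent coordinate vector.
   Subject embeddings are warm-started from, and Procrustes-aligned to, a
   group reference embedding.
3. **Phenotypes.** Substance-use facet composites (intent, access,
   family-developmental history) are item means, the trait-impulsivity scale
   is an item sum, and every score is winsorized at 3.5 SD. Demographics are
   encoded as a fixed covariate column set.
4. **Prediction.** Features are robust-scaled (median/IQR), the top 1,000
   features by univariate F statistic are selected, hyperparameters are tuned
   by nested 5-fold cross-validation within the discovery arm, and the final
   model is evaluated once on the held-out confirmation arm. Accuracy is the
   signed Pearson correlation r between predictions and observations, with
   100 r^2 as percent variance.
5. **Synthesis.** A synthetic-cohort generator produces data with the
   statistical structure the analysis assumes, so every stage is testable
   end to end without restricted data.

The full design crosses 4 outcomes x 2 outcome timings x 2 confirmation arms
x 3 model families = 48 specifications (`enumerate_specifications()`).

# Preprocessing

Defaults: FD threshold 0.3 mm, passband 0.008-0.09 Hz, second-order
Butterworth applied forward and backward, at least 10 minutes of retained
data required before connectivity is computed. The repetition time is a
required input (0.8 s in the synthetic configuration).

The order of operations is: censor mask, detrend/demean, nuisance
regression, interpolation, bandpass, correlation over retained frames. Two
choices here were genuinely open:

* **Interpolation.** Censored frames are filled by linear interpolation over
  retained frames (nearest-value extension at the sequence boundaries) purely
  so the filter sees a continuous signal; interpolated frames are never used
  in the correlation. Linear interpolation is the simplest scheme consistent
  with discarding interpolated data from analyses.
* **Fitting on retained frames.** The detrend line and the confound betas are
  estimated on retained (low-motion) frames only and then applied to all
  frames, so motion spikes cannot leak into the fits. Rank-deficient confound
  matrices (e.g. duplicated regressors) are handled by pivoted least squares;
  residuals are unaffected.

Zero-variance parcels are a hard error rather than being dropped silently:
the parcel count is structural (each parcel contributes `dims` embedding
features), so losing one would silently change the feature space.

# Node embeddings

The walk graph uses non-negative weights; negative correlations are clipped
to zero by default (an absolute-value policy is available) because random-walk
transition probabilities cannot be negative. Walks are second-order biased:
from current node v with previous node t, the probability of stepping to x is
proportional to w(v,x) times 1/p if x = t, 1 if x neighbors t, and 1/q
otherwise.

The latent dimensionality is 30 at full scale. All remaining settings are
package defaults in `embedding_config()`: p = q = 1, walk length 80, 10 walks
per node, window 10, 5 negative samples, 5 epochs, linearly decaying learning
rate. These are conventional settings for this family of embedding methods;
all are exposed in the configuration and recorded in output sidecars.

The skip-gram core is implemented in C++ with a self-contained RNG, so a
fixed seed gives byte-identical corpora and vectors on any platform in
single-threaded training. Negative samples are drawn from the
unigram^(3/4) corpus distribution via an alias table; the logistic function
is evaluated from a precomputed table (word2vec convention), which bounds
each gradient's accuracy at about 1e-3 — far below the stochastic variation
between seeds.

**Cross-subject alignment.** Raw latent dimensions are only identified up to
rotation, so predicting across subjects from raw coordinates would be
meaningless. Two mechanisms make dimensions comparable: every subject's
training is warm-started from a group reference embedding (trained on the
group-mean connectivity under a fixed seed), and the trained vectors are then
rotated onto the reference by orthogonal Procrustes (no scaling or
translation, which would distort cosine geometry). Cosine similarities among
a subject's own parcels — the model-implied connectivity — are provably
invariant to this rotation.

# Phenotypes

Composites are means of the facet's items at the given wave; the year-2 item
lists are subsets of baseline for intent and family-developmental history
(items not re-collected at the later wave) and identical for access. Missing
items are dropped from the mean by default (available-item mean); a
complete-case mode exists. Items are averaged on their raw scale — the
composite definition is literally an average of the relevant variables — with
an optional per-item standardization left to the caller.

Winsorization clamps to mean ± 3.5 SD with moments computed once on the full
available sample in a single pass (no re-estimation after clamping).
Computing the moments before the discovery/confirmation split technically
lets confirmation scores influence the clamp bounds; this is a deliberate,
documented simplification of a preprocessing step that precedes modeling.

The covariate encoder emits a deterministic 24-column set: sex, ethnicity,
17 race one-hot indicators, don't-know and refused indicators, a multiracial
flag (more than one race selected), household income and parental education.
Enumerating the standard demographic categories this way yields 24 columns,
not 23 as sometimes quoted for this covariate battery; the package asserts
its count only against its own shipped specification, and the column set is
configurable through the encoder's input table.

# Prediction protocol

Scaling (median/IQR per column, zero-IQR columns flagged and passed through),
selection (per-column simple-regression F statistic, ties broken by column
index, k = 1,000; when fewer columns exist all are kept with a warning) and
hyperparameter search all happen strictly within the discovery arm; the
confirmation arm is transformed with stored discovery parameters only. A
regression test asserts the trained model is byte-identical when
confirmation rows are mutated.

Hyperparameter grids:

* PLSR: components 1-10 (SIMPLS; one fit yields the whole component path).
* RIDGE: 20 penalties spanning 1e-6 to 1e6. The grid is spaced
  geometrically (linear in log10): literal linear spacing would place 19 of
  20 values above 5e4 and make the 1e-6 endpoint meaningless, which cannot
  be the intent of a grid quoted as running from 1e-6; a literal-linear mode
  is available (`grid_candidates("RIDGE", ridge_spacing = "linear")`).
* GBT: estimators {100, 200} x learning rate {0.01, 0.05, 0.10} x depth
  {3, 5} x l2 penalty {1, 10, 100} (36 settings), fit with xgboost.

Nested CV uses 5 outer folds; the inner fold count (unstated in the protocol
this mirrors) defaults to 5. Per outer fold, the inner grid search minimizes
mean inner-fold MSE; winning settings are then averaged across outer folds:
integer-valued settings round half away from zero, penalties average in
log10 space, and the learning rate snaps to the nearest grid value. Ridge
solutions come from an SVD path evaluating all 20 penalties at once with an
unpenalized intercept; PLSR is SIMPLS written in-package (no lightweight PLS
implementation was suitable as a dependency) and cross-checked in tests
against the least-squares limit and an independent implementation.

Evaluation reports the signed r; degenerate (zero-variance) predictions are
recorded as r = 0 with a flag rather than NA, matching the reporting
convention of near-null results. Confirmation subjects with missing outcomes
are dropped pairwise and counted. Network-level importance sums selected
embedding features by the network of their parcel (edge features, when used,
contribute half a count to each endpoint network; covariates are tallied
separately), so counts always sum to k.

# The synthetic cohort generator

The generator is one-way: it never reads pipeline outputs, so recovery tests
are honest. It emulates, per subject, four 5-minute runs at TR 0.8 s (1,500
frames), block-structured parcel covariance, FD traces with occasional
spikes, item tables at two waves, demographics and a matched two-arm split.

Defaults, chosen once as representative of resting-state cohort data at desk
scale: 90 parcels in 6 networks of 15; within-network correlation 0.35,
between-network 0.10; per-subject within-network coupling deviation SD 0.1
on the networks targeted by an effect; AR(1) coefficient 0.3; FD baseline
|N(0.12, 0.06)| mm with spike probability 0.05 and magnitude 0.8 mm (spiking
frames also receive additive signal artifacts); item loading 0.8 with 4
response levels.

Planted effects are defined at the latent level: each subject's coupling
deviation delta is drawn N(0, tau^2), and the latent facet score is
`eff * standardize(delta) + sqrt(1 - eff^2) * noise`, so the population
correlation between brain deviation and score equals the stated effect, with
per-timepoint multipliers for developmental contrasts. Item discretization
attenuates the observable ceiling slightly (about 3% at the default loading).

Two generation modes exist: full timeseries simulation (AR(1)-filtered
multivariate normal) and a fast mode that draws each subject's connectivity
directly from a Wishart distribution whose degrees of freedom match the
usable frame count — i.e. the sampling noise a real correlation estimate
from that much data would carry. Property suites use the fast mode.

What the generator does **not** emulate: spatial autocorrelation and
hemodynamics, non-Gaussian BOLD artifacts beyond motion spikes, site and
scanner effects, realistic item response models (a linear single-factor
model is used), or demographic confounding with the brain signal (available
as an option, off by default). Passing recovery tests therefore shows the
pipeline recovers the planted statistical structure, not that equivalent
accuracy would be reached on real cohort data.

# Problem sizes and run configurations

Simulation suites run at a deliberate desk scale chosen so the full
test battery completes comfortably on a single CPU: 90 parcels, 8 latent
dimensions, 400 subjects per arm, 20 generator seeds for calibration and
recovery (10 for the timing contrast), with embedding settings reduced
proportionally (walk length 30, 4 walks per node, window 4, 4 negatives,
2 epochs). At this scale the boosted-tree family uses a reduced candidate
grid (estimators {50, 100} x learning rate {0.05, 0.10}, depth 3, penalty 1),
2 inner folds and coarse histogram splits
(`options(neurocpm.gbt = list(tree_method = "hist", max_bin = 16))`); the
full 36-setting grid and its averaging rules are exercised by their own unit
tests. The acceptance script repeats the same study at 5 seeds.

# Numerical notes

* Edge vectorization is the strict upper triangle in row-major order with an
  explicit (i, j) index, and round-trips exactly through
  `edges_to_matrix()`.
* Correlations are clipped into [-1, 1] and matrices symmetrized against
  floating-point asymmetry before use.
* Fold assignment derives from the configuration seed; every specification
  derives its own stream by hashing the specification id with the global
  seed, so adding a specification never perturbs the others.
* The half-away-from-zero rounding used for integer hyperparameters is
  implemented explicitly (base R `round()` is round-half-even).
* Winsorization with fewer than 2 non-missing scores or zero SD is a
  pass-through.

# Known limitations

* Embedding determinism is guaranteed only in single-threaded training.
* The group-reference warm start couples subjects through the group mean
  connectivity; this is intentional (it defines the shared frame) but means
  embeddings are not independent across subjects in the strict sense.
* Winsorization moments are estimated before the arm split (see above).
* The generator's linear item model cannot exercise differential item
  functioning across waves; wave differences enter only through item-list
  shrinkage and effect multipliers.
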