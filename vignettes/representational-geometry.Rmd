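---
title: "Comparing representational geometries: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing representational geometries: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repgeom)
```

## The problem

High-level visual cortex — inferior temporal cortex (IT) in particular —
represents objects in a geometry with strong categorical structure:
animates cluster apart from inanimates, faces from bodies. Computational
models of vision produce feature vectors for the same stimuli. The two
kinds of system cannot be compared response-by-response (voxels and model
units do not correspond), but they can be compared at the level of their
*representational geometry*: the matrix of pairwise dissimilarities between
the response patterns the stimuli evoke. `repgeom` implements that
comparison pipeline end to end: RDM construction, rank-correlation
comparison with resampling inference, noise ceilings, category-cluster
modeling, noise equating, non-negative reweighting with stimulus
crossvalidation, and linear decodability.

## Dissimilarity metrics

Two metrics are supported, and they are two scalings of the same quantity:

* `correlation` — $d_{ij} = 1 - r(x_i, x_j)$, Pearson correlation across
  features, range $[0, 2]$;
* `sqeuclidean` — squared Euclidean distance after mean-centering each
  pattern and scaling it to unit norm, which equals $2(1 - r)$ exactly.

The squared-Euclidean form matters for reweighting (below): squared
distances are additive over concatenated feature blocks, correlation
distances are not. `compute_rdm()` enforces the preconditions (no constant
patterns under `correlation`; at least one feature) and names the offending
stimulus in its errors.

Single-feature representations — classifier decision values — have no
within-pattern correlation, so `correlation` is undefined for them. The
package's convention is to z-score the single feature across stimuli and
use squared differences (`sqeuclidean`). This preserves the additive
squared-distance algebra that the reweighting machinery relies on; any
monotone rescaling would leave the rank-based comparison statistics
unchanged anyway.

Missing cells are first-class: an RDM measured on a subset of the stimuli
is aligned with `embed_rdm()` (absent cells become missing), and every
statistic deletes missing cells pairwise. Missingness is represented by
`NA` with a validity flag in the vectorized form — never by sentinel
values. The canonical serialization is the row-major upper triangle,
`(1,2), (1,3), …`, used consistently by `vectorize()`, the category design
matrix, and file I/O.

## Kendall's tau-a

RDM comparison uses $\tau_A = (C - D) / \binom{m}{2}$ over the $m$ jointly
valid cells, with tied pairs counting as neither concordant nor
discordant. Because the denominator counts *all* pairs, a candidate that
predicts tied ranks (e.g. a binary category RDM) is penalized for its
ties; this makes $\tau_A$ conservative in exactly the situation where
Pearson or Spearman correlations would spuriously favor simplified
models. Counting is done in C++ by the merge-sort (Knight) algorithm in
$O(m \log m)$ — at 96 stimuli each comparison covers $m = 4560$ cells and
inference repeats it tens of thousands of times. The unit tests check the
fast path against an exhaustive $O(m^2)$ pair-enumeration oracle, with
ties, to $10^{-12}$.

## Resampling inference

* **Relatedness** (`permutation_test()`): the null applies a random
  simultaneous row/column permutation of the candidate's stimulus labels.
* **Uncertainty** (`bootstrap_stimuli()`): stimuli are resampled with
  replacement *within category strata*, so every resample has the study's
  category proportions. A duplicated stimulus would place diagonal zeros
  off the diagonal; those cells are masked, never treated as
  dissimilarities. (A consequence worth knowing: even a candidate
  identical to the reference bootstraps to $\tau_A$ slightly below 1,
  because duplicated stimuli create ties and $\tau_A$ counts ties against
  the correlation.)
* **Model comparison** (`compare_candidates()`): two-sided bootstrap
  p-values from the per-pair difference distributions, Benjamini–Hochberg
  step-up across all pairs to control the expected false discovery rate at
  0.05.

All resampling p-values use the add-one convention
$p = (1 + \#\{t^* \ge t\}) / (B + 1)$, which guarantees $p > 0$ and a
valid test at any $B$. Every resampling function takes an explicit
integer seed, records it in its output, and restores the caller's RNG
state, so results are reproducible call by call.

## Noise ceiling

No model can correlate with noisy single-subject RDMs arbitrarily well.
`noise_ceiling()` brackets the mean correlation attainable by the unknown
true model:

* **Upper bound**: a consensus RDM overfitted to the group. It starts from
  the element-wise mean of the rank-transformed subject RDMs. Since
  $\tau_A$ depends only on the candidate's *ordering* of cells, refinement
  searches over orderings: a greedy pass proposes swapping each pair of
  cells adjacent in the current order and accepts the swap when more
  subjects rank the pair the other way (an $O(S)$ incremental gain — an
  adjacent swap flips only that one pair's relative order). Passes repeat
  until none is accepted or `max_iter` (default 50) passes elapse. The
  returned bound is never below the initializer's mean correlation: ties
  in the rank-mean are broken only when breaking them helps, and the better
  of the initializer and the refined candidate is reported. The exact
  refinement procedure is a design choice — the published descriptions of
  this bound leave the iterative step unspecified — and any admissible
  refinement only tightens the overfitting, raising the bound.
* **Lower bound**: leave-one-subject-out — each subject's RDM correlated
  with the average of the *other* subjects' rank-transformed RDMs, then
  averaged. Restricted data make this an underestimate of the true model's
  correlation.

With only two subjects the bounds are computed but flagged with a warning:
the leave-one-out average then degenerates to the other subject, and the
bracket is weakly constrained. A caution established by simulation (and
asserted in the tests): for mutually *independent* subjects the lower
bound is near 0 but the upper bound is not — the overfit consensus retains
a mean correlation of roughly $(2/\pi)\arcsin(1/\sqrt{S})$ for $S$
subjects, a pure overfitting artifact that shrinks only as the ensemble
grows.

## Category-cluster model and CCI

Ten binary category predictors (animate, inanimate, face, human face,
non-human face, body, human body, non-human body, natural inanimate,
artificial inanimate) plus a constant are fitted to the vectorized RDM by
least squares on the valid cells. Coding is a design choice with two
observationally equivalent conventions; the package codes within-category
pairs as $-1$ so that a *positive* coefficient means a *tighter* cluster,
matching how clustering-strength bar charts are usually read. The
categoricality index (CCI) is the squared Pearson correlation between
fitted and observed cells — the proportion of RDM variance the category
model explains, in $[0, 1]$.

Inference: label randomization permutes the *entire hierarchical label
tuple* per stimulus (so containments — every face is animate, etc. — are
preserved and the constant predictor is untouched), rebuilding the design
each time; bootstrap CIs reuse the stratified stimulus bootstrap with the
same duplicate-masking rule. Rank-deficient designs (possible in small
bootstrap resamples) fall back to the minimum-norm solution and are
flagged.

## Noise equating

Comparing a noiseless model's CCI with a noisy brain's is unfair to the
brain. `equate_noise()` adds Gaussian noise to the model's features
(per-feature sd = $\alpha$ × that feature's sd) to create
`n_instances = 4` instantiations, computes their RDMs, and matches their
mean pairwise Pearson correlation $q_m$ to the target (e.g. the mean
pairwise correlation of single-subject brain RDMs). The correlation type
for $q_m$ is Pearson over jointly valid cells, consistent with how subject
RDM reliability is measured. Numerics: the noise deviates are drawn once
and scaled by $\alpha$, making $q_m(\alpha)$ deterministic and monotone
given the seed, so a bracketing bisection (geometric expansion of the
upper bracket, then bisection to `tol = 0.01`, `max_iter = 60`) converges
cleanly; the achieved $q_m$ and $\alpha$ are recorded on the result.

## Reweighting and remixing

Stretching a representation along its feature blocks by non-negative
weights changes its geometry. For normalized patterns under squared
Euclidean distance, the RDM of $\sqrt{w_k}$-scaled concatenated blocks is
exactly $\sum_k w_k \, \mathrm{RDM}_k$, so the fit happens at the RDM
level: `nnls_weights()` solves
$\min_{w \ge 0} \sum_{\text{pairs}} \big(d^{\mathrm{ref}} - \sum_k w_k d^{(k)}\big)^2$
with the Lawson–Hanson active-set algorithm (via `pracma::lsqnonneg`),
which satisfies the KKT conditions exactly at termination: components
anti-correlated with the residual receive weight exactly zero. Sign flips
of features never change distances, so non-negativity loses no
generality. The tests verify the additivity identity to $10^{-8}$ over
random cases and cross-check the solver against a two-weight grid-search
oracle.

Fitting weights on the same stimuli used to evaluate them overfits the
stimulus set. `crossvalidated_weighted_rdm()` therefore repeats: hold out
a stratified random subset (default 8 stimuli, balanced over strata, e.g.
4 animates + 4 inanimates), fit the weights on the cells among the
remaining stimuli only (a built-in assertion verifies no holdout cell
enters the fit), and predict the $\binom{8}{2} = 28$ holdout-internal
cells. Disjoint folds cannot tile all stimulus pairs, so folds with fresh
random holdouts repeat until every off-diagonal pair has at least one
prediction (cells predicted several times are averaged; `max_folds`
defaults to 50,000). The per-fold weights and achieved coverage are
attached to the result. The number of folds and the averaging rule are
design choices, recorded in the run manifest.

`combine_models()` puts heterogeneous models on equal footing before
combination: per model, center, project onto the leading `n_pcs`
principal components (default $\min(n-1, 95)$ — with $n$ stimuli the
covariance has at most $n - 1$ non-zero eigenvalues), rescale each block
to unit total variance, and concatenate; 27 models at 95 PCs give a
2565-dimensional representation. `train_discriminant()` learns linear
maximum-margin readouts (linear-kernel SVM, `e1071`) on labeled stimuli
*disjoint* from the evaluation set — an explicit leakage guard errors on
any overlap — and returns signed decision values as new single-feature
representations.

## Categorization performance

`kfold_accuracy()` measures linear decodability by stratified k-fold
crossvalidation (default $k = 12$: with 96 balanced stimuli every fold
holds out 8, 4 per class; the 48-stimulus subset tasks hold out 4 = 2 + 2).
Fold assignments are seeded and can be reused across models so accuracies
are paired. The SVM cost parameter defaults to 1 and is exposed.

Above-chance accuracy alone does not show *category* information — any
discriminable stimulus set supports some decoding. `dichotomy_null()`
retrains the classifier on random balanced dichotomies constructed
*orthogonal* to the true one: each pseudo-class takes exactly half of each
true class, so null dichotomies share no category signal. That
construction is this package's operational definition of
category-orthogonalized dichotomies; odd within-class counts fall back to
the nearest balanced split and are flagged. The null mean accuracy (≈ 0.5)
and the add-one p-value are both reported.

## The synthetic-data generator

`synthetic_spec()` mirrors the balanced study layout: 96 stimuli — 48
animate (24 faces, 24 bodies, each half human) and 48 inanimate (24
natural, 24 artificial) — 100 features, 4 subjects. Features are sums of
category-prototype directions: each category with non-zero *tightness*
contributes a random prototype (scaled by the tightness, in units of the
feature noise sd) to its members' rows, so subcategory members inherit
their ancestors' prototypes and tight categories form nested clusters —
the geometry the category model measures. Subject RDMs are the true RDM
plus independent symmetric Gaussian cell noise (default sd 0.15, chosen
to place 4-subject noise ceilings in the middle of the unit interval,
where real group ceilings typically sit), clipped to the metric's range.
Mixture references are $\sum_k w_k \mathrm{RDM}_k$ plus optional cell
noise, with the ground-truth weights attached.

What the generator does *not* emulate: spatially correlated measurement
noise, session effects, feature-level subject idiosyncrasies (subject
noise acts on RDM cells), non-Gaussian dissimilarity distributions, and
the specific geometries of real vision models. Passing tests therefore
demonstrate the pipeline's statistical correctness — calibration,
bracketing, recovery — not that any particular brain or model satisfies
these generative assumptions.

## Numerical choices and degenerate inputs

* RDM validation: symmetry within $10^{-8}$, exact-zero diagonal after
  symmetrization, symmetric missingness; loaders apply the same checks.
* Rank transform: average ranks for ties; missing cells stay missing.
* OLS fits: QR; rank-deficient designs use the SVD minimum-norm solution
  (singular values below $10^{-10}$ of the largest treated as zero) and
  set a flag.
* Ties in the noise-ceiling initializer are broken by cell index before
  refinement; the refined and unrefined candidates are both evaluated and
  the better reported.
* Fewer than 3 stimuli, empty categories, single-class training sets,
  constant patterns under correlation distance, and train/test overlap
  are all rejected with specific errors rather than propagating NaNs.

## Problem sizes

The test suite runs its calibration and bracketing simulations at reduced
stimulus counts (12–24 stimuli; 500 replicates for the type-I-error and
ceiling-bracketing suites, 100 seeds for recovery suites), which the
relevant statistical properties do not depend on; structural checks (95-PC
combination width, 12-fold holdout layout, embedding counts) run at the
full 96-stimulus layout. The acceptance script exercises the full layout
throughout.

## Known limitations

* The noise-ceiling refinement is a local search over adjacent
  transpositions; it can stop at a local optimum of the mean-$\tau_A$
  objective. Any such candidate still yields a valid upper bound estimate
  of the same construction, but a different refiner could return a
  slightly higher value.
* `compare_candidates()` treats candidates as fixed representations;
  subject-level random-effects inference is out of scope.
* Only the two stated dissimilarity metrics are provided (no Mahalanobis
  or crossvalidated distances), and only binary dichotomies for
  categorization.
* The crossvalidated assembly requires every stratum to be larger than its
  per-fold holdout share; very small strata need a smaller holdout.
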