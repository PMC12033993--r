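---
title: "Brain-state sequences from dynamic functional connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-state sequences from dynamic functional connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfncpm)
```

# The analysis in one paragraph

Resting-state fMRI component time courses (one per resting-state
network, RSN) are converted into a sequence of *brain states* per
subject: a Gaussian-tapered sliding window yields a windowed functional
connectivity (FC) vector per time step, the pooled windows of all
subjects are clustered into k discrete states, and each window is
assigned its nearest state. The resulting dominant-state sequences are
compared between groups in two complementary ways: (i) dwell-time
statistics (fraction of windows per state, mean contiguous run length)
with pooled two-sample t-tests, and (ii) *dichotomic pattern mining* —
frequent sequential patterns (ordered state tuples, gaps allowed) are
mined per group under a minimum-support constraint and partitioned into
group-unique and shared sets, after which subjects are classified from
one-hot encodings of pattern containment with random forests (RF) and
linear discriminant analysis (LDA) under repeated stratified
cross-validation. Because real cohort data are not bundled, a
synthetic-cohort generator with known switching-covariance structure
provides ground truth for every stage.

# Windowed functional connectivity

## Taper

`build_taper(width, sigma)` convolves a rectangle of `width` TR with a
unit-area Gaussian kernel (sd `sigma` TR, truncated at ±4σ), keeps the
central `width` samples and renormalizes to sum 1. Defaults are a 26-TR
window with σ = 3 TR at TR = 2 s — the common dFNC configuration for
~7-minute resting-state scans, where 26 TR ≈ 52 s trades temporal
resolution against estimator variance. As σ → 0 the taper approaches
the uniform window, which is the regime in which the windowed estimate
equals the textbook sample correlation (a unit-test oracle).

## Window bookkeeping

Windows use 0-based, half-open `[start, start + W)` indexing and are
advanced `step_tr` volumes. The window count convention is
`N_w = T − W` for step 1: the final window that would start at `T − W`
is dropped, so a 196-volume series with a 26-TR window yields exactly
170 windows — matching the convention of the dFNC tooling this
pipeline mirrors, whose dominant-state sequences advance "1 TR" 170
times. The alternative `T − W + 1` convention differs by one window
and is deliberately not used.

## Estimators

Per window, columns are centered with the taper-weighted mean and a
taper-weighted covariance is formed. Two estimators are exposed:

* **pearson** — the weighted correlation (`cov2cor` of the weighted
  covariance). Invariant to affine rescaling of any component.
* **glasso** — an L1-penalized precision matrix (graphical lasso,
  block coordinate descent with an inner coordinate-descent lasso;
  penalty on off-diagonal entries only), reported as partial
  correlations ρᵢⱼ = −Θᵢⱼ/√(ΘᵢᵢΘⱼⱼ). At λ = 0 the precision equals the
  direct inverse of the windowed covariance; for λ above the largest
  off-diagonal covariance the solution is exactly diagonal and all
  partial correlations vanish. Both limits are asserted in the tests.

The regularization strength is chosen once per subject: for each λ on a
10-point log-spaced grid in [0.01, 1], the mean held-out Gaussian
log-likelihood `log det Θ − tr(S_test Θ)` over 10 seeded random 80/20
splits of the subject's windows (fit on the mean training-window
covariance, scored on the mean held-out covariance) — the repeat count
mirrors the "repeated L1" convention of the reference tooling, whose
exact procedure is not published.

One numerical caveat found while validating: *elementwise*
monotonicity of |partial correlation| along the λ path holds only
approximately (entries near the soft threshold can rise by ~2·10⁻³
between grid points; the identical fluctuation is reproduced by other
graphical-lasso implementations on the same input). The mean
off-diagonal magnitude is strictly monotone, and that is what the test
asserts elementwise only up to a 5·10⁻³ slack.

Connectivity values are Fisher z-transformed before clustering
(`atanh`, inputs clipped at |r| ≤ 1 − 10⁻⁷), toggleable — common dFNC
practice that makes city-block distances less dominated by
near-ceiling correlations.

# Brain states

## k-medians clustering

"City distance" k-means is implemented as k-medians: assignment by
minimal L1 distance, centroid update by the coordinate-wise median (the
L1-optimal centroid; the mean is not). Five replicates from seeded
k-means++-style initializations (distance-proportional seeding under
the model metric) are run and the replicate with least total
within-cluster distance kept; empty clusters are reseeded at the point
farthest from its nearest centroid. Windows of all subjects are pooled
with no exemplar subsampling pass — at desk scale (thousands of
windows × 55 pairs) the two-stage exemplar scheme of large-cohort
tooling is unnecessary. Final states are relabeled in descending
occupancy order, making labels deterministic; note this means the
label → phenotype mapping (hypo/hyper/anticorrelated) can differ
between runs and must be established post hoc, e.g. by centroid
connectivity strength or, on synthetic data, by permutation matching
against ground truth.

## Choosing k

The cluster validity index for each k is the total within-cluster
distance divided by the *mean* pairwise centroid distance. Normalizing
by the pair count matters: dividing by the *total* pairwise distance
(which grows ~k²) makes the index decay mechanically for any data, so
every curve shows a spurious elbow at the smallest interior k.
With the mean-pairwise denominator the index inherits the elbow of the
within-cost curve: on three well-separated synthetic states it kinks
sharply at k = 3, while structureless data decay smoothly. The elbow is
the interior k with maximal positive second difference; when that
maximum is below 10% of the curve's range the choice is flagged
low-confidence (a near-linear curve has no elbow).

## Dwell statistics and group tests

A run-length scan yields, per state: fraction of windows, mean
contiguous run length in windows and in seconds (`× step × TR`), run
counts, transition count and the empirical transition matrix (rows
with no outgoing transition are NA and flagged). Both the fraction and
the mean-run-length readings of "dwell time" are computed, since
published usage varies. Group comparisons use the pooled-variance
two-tailed t-test, evaluable from raw samples or from summary
statistics (mean, sd, n) so that printed cohort tables can be checked
directly; p-values are reported uncorrected — matching the practice of
the study design this mirrors — with a Holm-adjusted column emitted
alongside for transparency.

# Dichotomic pattern mining

Dominant-state sequences are run-length compressed by default
(`[1,1,2,2,1] → [1,2,1]`): with gaps-allowed containment over raw
170-step sequences, nearly every short tuple is trivially contained in
every subject and pattern counts explode; compression preserves
exactly the transition structure that sequential patterns are meant to
express. A pattern is an ordered tuple of ≥ 2 state labels (a single
state is not a *sequential* pattern); containment allows gaps and is
decided by greedy leftmost matching, which is exact for subsequences.
Mining is depth-first prefix projection with antimonotone pruning
(asserted at every extension); sequence-level support (a subject
counts once) must reach `ceiling(min_support × n)` within the group,
with min_support = 0.05 by default, computed per group on that group's
n per the support definition over "either group". Patterns are capped
at length 10 by default for tractability and interpretability. The
dichotomic partition (unique-to-A / unique-to-B / shared by exact
tuple equality) asserts |A\B| + |B\A| + |A∩B| = |A∪B| on every run.
The miner is verified against an exhaustive subsequence enumerator on
hundreds of randomized instances.

# Classification

One-hot encoding marks pattern containment per subject (same
compression convention as at mining time). Patterns unique to one
group may be absent from the other group's subjects — that asymmetry
is the signal, so constant-in-one-group columns are retained.

Protocol: seeded stratified 80/20 split; grid-search tuning by inner
5-fold CV on the training split, with the inner CV repeated 5 times
and accuracies averaged (a single 5-fold accuracy at n ≈ 40 is too
noisy to order grid points); held-out test metrics for the tuned
model; then 100 repetitions of stratified 10-fold cross-validation
over the full cohort with per-repetition seeds, pooling fold
predictions within each repetition before computing accuracy, rank
AUC, recall, precision and F1 (per-fold metrics at n ≈ 5 per fold are
degenerate). Models: random forest (grids: trees {100, 300, 500}, max
depth {∞, 4, 8} via the node cap min(2^depth, n), min leaf {1, 3})
and binary Gaussian LDA (shrinkage {none, auto}). "none" is genuinely
unregularized and *errors* on a singular pooled covariance (rcond <
10⁻¹⁰) rather than being rescued with a ridge: a near-singular rescue
silently interpolates at p ≈ n, a pathology that inner CV on the
smaller training split cannot detect; erroring lets the grid fall back
to "auto" — Schäfer–Strimmer-style shrinkage of the off-diagonal
toward zero, with a 10⁻⁸ diagonal floor so perfectly separating
(zero-within-class-variance) features remain usable. If a
shrinkage-free fit tuned on the training split turns out singular on
the full cohort, the final fit falls back to "auto" and the reported
tuned parameters say so.

Importance rankings are emitted for both models, clearly labeled,
since "most important" is model-specific: RF mean impurity decrease;
LDA absolute discriminant coefficients standardized by the pooled
within-class sd; each normalized to sum 1, top 10 reported.

# The synthetic cohort

The generator emulates the study geometry: C = 11 RSN component time
courses, T = 196 volumes, TR = 2 s, k = 3 latent states. Rows are
drawn i.i.d. given a hidden volume-resolution Markov path (initial
state from the chain's stationary distribution), from zero-mean
multivariate normals with state-specific SPD correlation matrices,
plus isotropic noise (sd 0.2 by default — mild measurement noise
relative to unit-variance components). State profiles: *hypo* (all
|off-diagonal| ≤ 0.1), *hyper* (one-factor model, mean off-diagonal
≈ 0.55) and *anticorrelated-block* (signed one-factor loadings, two
blocks coupled ≈ +0.45 within and ≈ −0.45 across; SPD by
construction). Default dynamics: the control-like group has
self-transitions 0.97 everywhere (mean dwell ≈ 33 volumes ≈ 66 s,
within the range reported for resting-state brain states) and uniform
stationary occupancy; the impaired-like group has self-transition 0.99
for the hypo-connected state plus elevated inflow, biasing occupancy
toward it — a qualitative analogue of impaired cohorts dwelling in
sparsely connected states. No empirical transition matrices are
published for the mirrored study, so these dynamics are qualitative
analogues, chosen once. The master seed expands into fixed per-subject
substreams, so subject i is bit-identical regardless of cohort size.

The generator deliberately omits features of real data: no temporal
autocorrelation within a state (rows i.i.d. makes the windowed
estimator consistent; an AR option would be a separate extension), no
hemodynamic convolution, no scanner drift or motion, Gaussian
marginals, and an exactly first-order hidden chain. Passing tests
therefore demonstrate *method correctness and recoverability under the
model's own assumptions*, not performance on real fMRI.

## Motif injection and the end-to-end recovery condition

For classification tests a group-unique transition motif can be
injected: with a given probability a block `rep(motif, each =
hold_volumes)` overwrites the hidden path at a random position. The
end-to-end recovery condition uses 25 + 25 subjects, the motif
2→3→2→3 (alternating the two most separated states, so boundary
flicker between adjacent centroids cannot mimic it), insertion
probability 1, and hold 30 volumes — longer than the 26-TR window, so
each motif state dominates whole windows and survives into the
dominant-state sequence. Mining for this condition uses min_support
0.4 and max_length 4: at n = 25 a 0.05 support threshold means "2
subjects", which mines thousands of near-duplicate idiosyncratic
patterns whose collinearity dilutes any importance measure; a
group-typical support level and a short length cap isolate the planted
pattern, which is the regime the recovery property is about. These are
condition parameters, not changed defaults — the pipeline's defaults
remain the study settings (0.05, length ≤ 10).

The planted motif is checked against the *cluster-space* key obtained
by mapping its true state labels through the permutation that best
matches assigned to ground-truth window states: occupancy-based
relabeling is deterministic but can permute state identities between
cohorts.

# Numerical and implementation choices

* Ties in nearest-centroid assignment break toward the lower state
  label; replicate seeding is `seed + replicate − 1`.
* Zero-variance columns inside a window abort with subject, window and
  column named (upstream data defect, not recoverable here).
* The t-test with zero pooled variance returns t = 0, p = 1 for equal
  means and p = 0 with a warning otherwise; groups of n < 2 error.
* Problem sizes used by the test-suite recovery checks — 30-subject
  default cohorts, 50-subject motif cohorts, 200 miner-oracle
  instances, 10⁴ t-test null simulations — were chosen to keep Monte
  Carlo bands comfortably inside the asserted tolerances.
* All randomness flows from explicit integer seeds; reports are
  reproducible bit-for-bit given the same configuration.

# Known limitations

* The glasso path refits every window at the selected λ; for C ≫ 20
  components a warm-started path would be preferable.
* The elbow flag follows the 10%-of-range rule; within-cost curves of
  unstructured data are convex, so the flag fires mainly on
  near-linear curves, and k* on such data should be read together with
  the flag and the curve, not alone.
* LDA is binary-only, matching the two-way dichotomies of the design;
  multi-class tasks are out of scope.
* With per-group support thresholds near one subject (small n at
  support 0.05), "group-unique" patterns are sensitive to single
  subjects' label noise; the vignette's recovery condition raises the
  support precisely for that reason.
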