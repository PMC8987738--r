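---
title: "Multimodal classification with multiple kernel learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal classification with multiple kernel learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkfusion)
```

# The problem

Detecting mild cognitive impairment (MCI) — a prodromal stage of possible
Alzheimer's disease — from neuroimaging is a small-sample, high-dimensional
classification problem: a cohort of a few hundred participants, described by
feature sets whose dimensions range from about a hundred (regional
gray-matter volumes from structural MRI) to tens of thousands (sensor
covariances from resting-state MEG). The two modalities plausibly carry
complementary information — atrophy versus electrophysiological change that
may precede atrophy — so the interesting methodological question is *where*
to combine them:

* **Early** combination concatenates the (normalized) features of all
  modalities and trains a single classifier;
* **Intermediate** combination projects each modality into its own kernel
  and lets a multiple kernel learning (MKL) algorithm weight the kernels;
* **Late** combination trains one classifier per modality and combines
  their continuous decision outputs with a second-level MKL — a form of
  stacked generalization.

`mkfusion` implements all three pipelines around a single classifier
(EasyMKL), a balanced repeated cross-validation protocol with matched
splits, a confound-as-kernel mechanism, and a synthetic cohort generator
that makes the whole chain testable without access-restricted clinical
data.

# The classifier

## Kernels

Each feature set is z-scored across training participants and projected
into a linear kernel: entry $(i,j)$ is the inner product of the feature
vectors of participants $i$ and $j$. Linear kernels are the appropriate
choice when features far outnumber participants; the kernel is a
participants × participants matrix regardless of modality dimension, which
is what makes kernel combination across incommensurate modalities natural.

Kernels are min–max normalized to $[0,1]$ using the extremes of the
*training* block, with the identical affine map applied to the test block.
Test entries beyond the training range are deliberately not clipped:
any renormalization that consulted the test block would leak test
information. Two consequences are documented rather than hidden:

* the affine shift does not preserve positive semi-definiteness, so the
  downstream solver must tolerate mildly indefinite (regularized) problems;
* kernels are not centered anywhere in the pipeline.

## EasyMKL

Given base kernels $k_1,\dots,k_N$ and labels $y_i \in \{-1,+1\}$, the
combined kernel is
$$K(x, x') = \sum_{n=1}^{N} \eta_n\, k_n(x, x'), \qquad
  \sum_n \eta_n = 1,\ \eta_n \ge 0,$$
and the decision function is
$$f(x) = \sum_{i=1}^{L} \alpha_i\, K(x, x_i) + b .$$

The weights and coefficients come from a quadratic program over
per-example coefficients $\gamma$ constrained to the *bi-class simplex*
($\gamma \ge 0$, summing to one within each class):
$$\min_{\gamma}\ (1-\lambda)\,\gamma^\top Y \bar K Y \gamma
  + \lambda \lVert\gamma\rVert^2 ,$$
with $Y = \mathrm{diag}(y)$ and $\bar K = \sum_n k_n$. The fit proceeds in
two stages: solve the QP with the plain kernel sum, read off the kernel
weights as $\eta_n \propto \gamma^\top Y k_n Y \gamma$ (normalized to the
simplex; a negative raw value, possible only for indefinite normalized
kernels, is truncated to zero), then re-solve the same QP with the
$\eta$-weighted kernel. The expansion coefficients are
$\alpha_i = \gamma_i y_i$.

The regularization weight $\lambda \in [0,1]$ trades the margin objective
against shrinkage towards uniform per-class coefficients: $\lambda = 1$
gives exactly $\gamma_i = 1/n_\pm$ within each class (the solver reproduces
this closed form exactly), while $\lambda = 0$ is the pure margin objective
and is admitted but sensitive to training outliers.

**Bias convention.** The intercept is placed at the midpoint of the
$\gamma$-weighted class margin means, $b = -\tfrac12(m_+ + m_-)$ with
$m_\pm = \sum_{i \in \pm} \gamma_i\, (K\alpha)_i$, so margins are symmetric
about zero on the balanced training sets this protocol guarantees. The
original algorithm's bias convention is not uniquely determined by its
published description; none of the package's comparisons depend on the
absolute value of $b$.

**Solver.** The QP is solved by an accelerated projected-gradient method
(FISTA with function-value restart) over the product of the two class
simplices, with fixed step $1/\lVert H\rVert_2$, a deterministic uniform
feasible start, and convergence tolerance $10^{-8}$ on the iterate change.
There is no random initialization, so fits are bit-reproducible. The
method only requires projections onto the simplex, is robust to the mild
indefiniteness left by min–max normalization, and is verified in the test
suite against a brute-force grid search on the simplex and against an
independent interior-point solver.

With a single kernel the procedure reduces to a kernel margin classifier
(KOMD), and the three combination pipelines coincide exactly — the package
special-cases the single-set Late pipeline to return the stage-1 margins so
this identity holds to machine precision.

# MEG feature extraction

The canonical six bands are Delta 2–4, Theta 4–8, Alpha 8–12, Beta 12–30,
low Gamma 30–48 and high Gamma 52–86 Hz (the gap around 50 Hz avoids mains
interference). For one recording and one band the fixed pipeline is:

1. **Band-pass**: order-5 Butterworth high-pass at the low edge, then
   order-5 low-pass at the high edge, each applied forward–backward
   (zero phase). Zero-phase filtering keeps epochs aligned across bands at
   the cost of squaring the amplitude response; at 10 Hz the composite
   alpha-band response is about 0.78 rather than the ~0.88 of a single
   pass, and `bandpass_response()` exposes the exact curve so tests assert
   against it instead of a nominal figure.
2. **Epoching** into 2-s segments, dropping the trailing remainder
   (120 s at 500 Hz gives exactly 60 epochs).
3. **Bad-epoch marking**: an epoch is flagged when the log of its total
   variance exceeds the median by more than 3 scaled median absolute
   deviations (consistency constant 1.4826) across epochs. This is a
   deliberate robust stand-in for a full artifact detector; it is not a
   reimplementation of any specific toolbox.
4. **Concatenation** of the non-bad epochs in original order.
5. **Outlier clipping**, per channel: samples outside
   $\mathrm{median} \pm 3 \times 1.4826 \cdot \mathrm{MAD}$ are replaced by
   the nearer boundary. When the MAD is zero the boundary collapses to the
   median, the continuous limit of the rule, so isolated spikes on an
   otherwise flat channel are removed rather than kept.
6. **Covariance**: the sample covariance across channels with per-channel
   mean removal and $n-1$ denominator (the unbiasedness convention; the
   choice is stated because nothing downstream depends on it).

Band power is kept on its absolute scale: relativizing each band to total
power would also remove any true between-group power differences. The
overall signal-strength differences that absolute power admits (heads sit
at different distances from the sensor array) are instead handled by the
confound mechanism, which includes the *squared* mean sensor distance
because magnetic field strength falls off with at least the square of
distance.

Variance features are the covariance diagonal (one value per channel);
covariance features are the strict upper triangle in fixed row-major order,
of length $p(p-1)/2$ — 5151 for a 102-channel magnetometer-like array,
20 706 for 204 gradiometer-like channels. Vectorization is bijective:
`unvectorize_features()` restores the matrix exactly.

An optional PCA step (fit on training rows, applied to held-out rows)
retains the smallest number of components explaining 95% of variance,
mirroring the common dimensionality-reduction variant of this analysis.

# Combination pipelines and confounds

All three pipelines consume the same split plan, so their outputs are
directly comparable:

* **Early**: z-score each feature set on the training rows, concatenate
  columns, build one normalized linear kernel, fit the classifier.
* **Intermediate**: one normalized kernel per feature set, single EasyMKL
  fit across them.
* **Late**: stage 1 fits one single-kernel classifier per set. Out-of-fold
  margins for the training rows come from 5 stratified inner folds (no
  training example is ever scored by a model that saw it); the held-out
  test set is scored by a model refit on the full training set — the
  standard stacking choice; averaging the inner-fold models instead is a
  known alternative and was deliberately not made the default. Stage 2
  treats each margin vector as a one-column feature set — z-scored,
  kernelized, min–max normalized like any modality — and fits a meta-level
  EasyMKL over these decision kernels. The two stages have independent
  regularization weights, and `tune_lambda()` can tune each by inner
  balanced cross-validation (grid search scored by the same balanced
  accuracy used for outer evaluation; ties go to the smallest $\lambda$,
  the weaker penalty on informative kernels).

**Confounds as kernels.** Eight potential confounds — site, sex, age, time
of day, mean and SD head translation, squared sensor distance, education —
each become a single-feature kernel appended to any pipeline
(`with_confounds()`), rather than being regressed out of the features.
Site and sex are encoded 0/1 because a single-feature linear kernel needs a
numeric input. The cognitive screening score (MMSE) is excluded by
construction: it informs the patient diagnosis, so using it as a predictor
would be circular. Comparing a model *with* confounds against the
confound-only baseline is the package's way of asking whether a modality
adds information beyond what the confounds already predict.

# Evaluation protocol

**Balanced splits.** With unequal group sizes, the minority class is
partitioned into $k$ folds; each fold's training set is the other $k-1$
minority folds plus an equal-sized subset of the majority class, so
training is always exactly balanced, and the test set receives the held-out
minority fold plus all remaining majority participants. The majority class
is folded as well and a member's own fold is excluded from its training
draw, which guarantees every participant is tested at least once per
repetition. Because test sets are imbalanced, accuracy is reported
*balanced* (mean of per-class accuracies, in percent): any constant
classifier scores exactly 50.

**Matched repetitions.** Cross-validation is repeated R times (1000 at
study scale; 100 in this package's tests, a size at which the protocol's
qualitative behaviour is stable while the suite stays fast); within a
repetition every method sees identical split plans, so per-repetition
accuracy differences are meaningful. `paired_difference()` reports the mean
difference and the percentage of repetitions in which one method was
strictly better — an approximation to the reliability of an improvement,
not a formal hypothesis test. Exact ties are reported both ways (excluded,
or contributing one half); per-repetition accuracy is the average over the
$k$ folds of fold-level balanced accuracy (averaging fold accuracies, not
pooling predictions, is the default and the alternative is noted).

**A subtlety about "unbiased at chance".** The protocol is unbiased in the
sense that its *expected* balanced accuracy over independent draws of
label-independent features is 50%. Conditioned on a single fixed null
dataset it is not: the dataset's accidental class gap is shared between the
disjoint train and test subsamples of every split (with a negative sampling
correlation), and repeated splitting cannot average it away — single fixed
null datasets of 120 participants can sit several points above or below
50%. The package's calibration checks therefore draw fresh
label-independent features for every fold, which is also what a noise
*simulation* of the protocol means; passing them shows the procedure adds
no systematic bias, not that any one null dataset will score exactly 50%.

# The synthetic cohort generator

The generator emulates a two-site MCI/control study of 163 controls and
144 patients (sizes configurable). Per-group marginal distributions of the
demographic and acquisition variables are built in as defaults: e.g.
education 14.5 ± 4.4 years in controls versus 11.0 ± 5.2 in patients, age
71.2 ± 7.0 versus 72.8 ± 6.8, site and sex as per-group Bernoulli draws,
sensor distance 113.0 ± 1.5 versus 113.3 ± 2.3 mm ×10³. Variables are
drawn independently within group — only marginals are specified, and no
between-variable correlation structure is asserted because none is known to
us; this is a declared simplification, not an inference. Missing cells are
inserted at per-variable rates (a few missing cognitive scores, more
missing motion summaries) to exercise the imputation path:
nearest-neighbour with one neighbour, distances computed over shared
observed variables *after* per-variable standardization, since raw
Euclidean distance would be dominated by the largest-scale variable
(sensor distance, in mm).

MEG-like recordings are sums of independent band-limited Gaussian
processes (white noise through the package's own band-pass, so in-band
energy is guaranteed by construction), with a group effect injected as a
*shared* band-limited component on a chosen channel subset of patients —
perturbing both per-channel power and between-channel covariance in the
target band only. Spike artifacts for clipper tests are isolated samples
at 10× the channel SD, chosen to be unambiguous targets.

What the generator does **not** emulate: realistic sensor covariance
structure or 1/f spectra, site-specific shielded-room noise, head-geometry
or forward-model effects, correlated confounds, or any vendor file format.
Tests passing on this generator therefore demonstrate correctness of the
statistical machinery and the qualitative behaviour of combination
strategies — not clinical-grade accuracy figures, which are data-bound and
out of scope.

## The canonical multimodal simulation

`simulate_multimodal_cohort()` freezes the package's reference problem for
studying combination strategies, with 60 participants per group:

* an MRI-like set of 110 features (the atlas ROI count) with 10
  "atrophied" features at a focal standardized deficit of $d = 0.8$ —
  few, individually strong features;
* an MEG-like set of 2000 features with 60 informative at $d = 0.45$ —
  a desk-scale stand-in for the 20 706 covariance features: many more,
  individually weaker features, statistically independent of the MRI noise
  so the modalities are complementary;
* optional pure-noise sets of 500 features each.

These sizes were chosen once, on the reasoning above, as a realistic
miniature of the modality asymmetry that makes Early combination dilute a
strong compact modality inside a large weak one, Intermediate combination
recover it by kernel weighting, and Late combination additionally resist
uninformative kernels at the decision level. The acceptance suite runs the
full matched protocol on this problem (R = 100, $k = 5$, $\lambda = 0.5$
fixed) and checks exactly those orderings; it does not assert any numeric
accuracy value.

# Numerical choices, degenerate inputs, limitations

* QP tolerance $10^{-8}$, deterministic start; $\lambda = 1$ handled
  exactly; negative raw kernel weights truncated to zero before simplex
  normalization.
* Zero-SD features (e.g. a binary confound constant within a fold) are
  standardized with scale 1, mapping to all-zero, instead of erroring.
* A constant kernel (max = min) is an error — it carries no information
  and cannot be min–max normalized.
* Margins of exactly zero predict the positive class (documented tie rule).
* Epoching drops trailing remainders; recordings shorter than one epoch
  are an error; bad-epoch marking needs at least 3 epochs; all-bad
  recordings are an error rather than an empty series.
* The broadband 0.5–98 Hz pre-filter and 500 Hz down-sampling step of a
  real acquisition pipeline is assumed already applied; synthetic data are
  generated at 500 Hz directly.
* The stage-1 inner fold count (5) and the full-train refit for test
  margins are fixed design choices; alternatives (more folds, fold-model
  averaging) would be easy extensions but are not implemented as options.
* No probability calibration: margins are used raw, and only their signs
  and orderings matter anywhere in the package.
* No alternative stage-1 learners; the pipeline interface leaves that
  extension open.
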