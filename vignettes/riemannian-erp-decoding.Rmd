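---
title: "Single-trial ERP decoding with xDAWN and Riemannian geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trial ERP decoding with xDAWN and Riemannian geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Visual stimuli evoke stereotyped EEG responses (visual evoked
potentials) that are classically studied by grand averaging many trials.
Averaging discards single-trial and single-subject information, so a
complementary approach is to *classify* single epochs: given one
500-ms post-stimulus EEG segment from 12 scalp electrodes, decide which
of two stimulus classes produced it.  `riemerp` implements the
covariance-based decoding pipeline that dominates this problem class in
the BCI literature, together with a standardized distributed inverse
(sLORETA) so the same decoding can be run on cortical source
activations, and a synthetic multi-subject ERP generator so every stage
is testable without access to recordings.

## The decoding model

**Evoked prototypes and xDAWN.**  For class $k$ with trials
$X_i \in \mathbb{R}^{E \times T}$, the prototype is the grand average
$P^{(k)} = \frac{1}{N_k}\sum_i X_i$.  An xDAWN spatial filter
$w \in \mathbb{R}^E$ maximizes the generalized Rayleigh quotient

$$\frac{w^\top P^{(k)} P^{(k)\top} w}{w^\top X X^\top w},$$

where $X$ concatenates all trials of both classes along time.  The $F$
leading generalized eigenvectors of
$(P^{(k)}P^{(k)\top},\, XX^\top)$ per class form the bank
$W = [W_0, W_1] \in \mathbb{R}^{E \times 2F}$.  Filters concentrate
evoked energy relative to total signal energy, which is what transfers
across subjects.

**Augmented-trial covariance.**  Each trial is represented by the
covariance of the $4F$-row stack
$\tilde Z_i = [W_0^\top P^{(0)};\, W_1^\top P^{(1)};\, W^\top X_i]$,
estimated as $\Sigma_i = \tilde Z_i \tilde Z_i^\top / T$ and shrunk
toward a scaled identity (OAS by default, Ledoit-Wolf optional) so it
is well conditioned.  The prototype rows make the covariance sensitive
to the temporal covariation of a trial with both class templates.  With
$E = 12$ electrodes we use $F = 3$, so $\Sigma_i$ is $12 \times 12$.

**Tangent-space mapping.**  Covariances live on the SPD manifold.  With
$\Sigma_{\mathrm{ref}}$ the geometric (Fréchet/Karcher) mean of the
training covariances, each matrix is mapped to
$\Phi(\Sigma) = \Sigma_{\mathrm{ref}}^{1/2}
\log\!\big(\Sigma_{\mathrm{ref}}^{-1/2} \Sigma
\Sigma_{\mathrm{ref}}^{-1/2}\big) \Sigma_{\mathrm{ref}}^{1/2}$ and
half-vectorized after whitening, with off-diagonal weight $\sqrt 2$, so
the Euclidean norm of the feature vector equals the affine-invariant
Riemannian distance to the reference (dimension $n(n+1)/2 = 78$ for
$n = 12$).  The printed vectorization formula in the source literature
is typographically inconsistent; the convention here is the one that
makes the map an isometry, which is what the construction is for and is
verified by test.

**Classifier.**  L2-regularized logistic regression on the tangent
vectors (ridge `glmnet`, penalty $\lambda = 1/n_{\mathrm{train}}$, the
conventional unit-strength choice; `standardize = FALSE` so features
are used on their natural tangent-space scale).  Decision scores are
linear-predictor values; class 1 is predicted when the score is
positive.

**Source space.**  The minimum-norm operator
$T(\alpha) = K^\top (KK^\top + \alpha I)^{-1}$ for lead field
$K \in \mathbb{R}^{E \times 3M}$ is standardized per voxel by the
$3\times3$ diagonal blocks $\Sigma_\ell$ of the resolution matrix
$T(\alpha)K$: $\hat J^{\mathrm{std}}_\ell = \Sigma_\ell^{-1/2}
T(\alpha)_\ell X$.  This standardization gives exact localization of a
single noiseless source (verified 100/100 in the acceptance suite at
$\alpha = 10^{-8}$).  Voxel activations (orientation norms) are averaged
per atlas-style region and the resulting region-by-time matrices are fed
to the identical sensor-space pipeline ($F = 3$).  Orientation *norms*
are used rather than signed components; signed components can be
obtained from `apply_inverse()$timecourses` if needed.  Real head-model
lead fields and label files can be supplied through `lead_field()`, but
tests use synthetic lead fields only.

## Cross-validation design

* **Inter-subject:** leave-one-subject-out (LOSO); all supervised
  stages — xDAWN filters and prototypes, CSP filters, the tangent
  reference, the classifier — are fitted on the training subjects only.
  Fold accuracies (one per held-out subject) are the sampling unit for
  distributional comparisons.
* **Intra-subject:** stratified, seeded 4-fold cross-validation run
  independently per subject; one accuracy per subject × fold.
* Metrics: pooled confusion matrix (raw counts summed over folds),
  accuracy, MCC (defined 0 when a marginal is zero), ROC/AUC with
  averaged-rank tie handling (so trapezoidal AUC equals the
  Mann–Whitney identity $U/(n_+ n_-)$ exactly), precision–recall with
  step-wise average precision.
* Distribution comparisons use a two-sided Mann–Whitney U test on fold
  accuracies (`compare_accuracy_distributions()`), with `p = 1` and a
  warning when every value is tied.

## The synthetic generator

`simulate_epochs()` emulates a two-class passive visual paradigm:
15 subjects, 96 trials of class 0 and 192 of class 1 per subject,
12 standard 10–20 electrodes, 1-s epochs (−500 ms to +500 ms) at
512 Hz.  Class templates are sums of Gaussian bumps: class 0 a large
monophasic positive deflection at 100 ms (8 µV, SD 15 ms) plus a 220-ms
bump; class 1 a smaller biphasic −3/+3.5 µV pair at 100/140 ms plus the
220-ms bump.  Topography is occipitally dominant (gains O 1.0 ≫ P 0.55
> C 0.3 > F 0.15).  The recording rate in the emulated design was
2048 Hz; 512 Hz is the package default for desk-scale speed and the
rate is configurable up to that value and beyond.

Each trial is $A_s \cdot S(\text{jitter}) + \text{noise}$:

* $A_s = R_s\,\mathrm{diag}(g_s)$ is a per-subject spatial mixing:
  lognormal channel gains ($\sigma_{\log} = 0.4$) composed with a random
  orthogonal perturbation of the identity (scale 0.25).
* Per-subject global amplitude gain (lognormal, $\sigma_{\log} = 0.3$)
  and latency offset (SD 25 ms); per-trial amplitude
  ($\sigma_{\log} = 0.25$) and latency (SD 10 ms) jitter.
* Background noise: per-channel $1/f^\gamma$ filtered Gaussian noise
  ($\gamma = 1$, SD 4 µV) plus white sensor noise (SD 1 µV).

The subject-variability scale deserves comment because it is the one
place the emulated design is silent.  Real ERP datasets show
between-subject P100 latency scatter of a few tens of milliseconds and
substantial topographic/gain differences; the defaults above are set in
that range, and deliberately large enough that the structural contrasts
the design predicts actually hold in simulation: pooled single trials
are far harder to separate than within-subject trials, spatially robust
covariance features transfer across subjects better than raw vectorized
amplitudes, and the occipital triad carries most of the discriminative
signal.  The generator reproduces *orderings*, not the absolute
accuracies of any particular recording; nothing about real electrode
physics (volume conduction from a head model, artifacts, non-stationary
rhythms) is simulated, so passing tests demonstrate correctness of the
pipeline and the predicted qualitative structure, not field performance.

`simulate_source_epochs()` provides the source-space ground truth: a
random well-conditioned lead field (condition number ≤ 10⁴, redrawn up
to 20 times), one designated active voxel per class carrying the class
waveform along a fixed random orientation, white sensor noise only.
This is an artificial construct for validating the inverse — labelled
synthetic throughout — not a head model.

## Numerical choices

* **Filtering:** 4th-order Butterworth band-pass applied
  forward–backward (`signal::filtfilt`), i.e. zero-phase with squared
  magnitude response; band edges validated against the Nyquist range.
* **Baseline:** the mean over the pre-stimulus window is *subtracted*;
  epochs are generated on −500…+500 ms so correction precedes cropping
  to [0, 500) ms.
* **Cropping:** half-open intervals, sample kept iff
  $t_{\mathrm{start}} \le t < t_{\mathrm{end}}$ (256 samples for
  [0, 0.5) s at 512 Hz).
* **Eigenvector conventions:** deterministic sign (largest-magnitude
  entry positive); generalized eigenproblems solved via Cholesky of the
  denominator with an escalating trace-scaled ridge
  (0, 10⁻¹⁰, 10⁻⁸, 10⁻⁶) for degenerate inputs.
* **Geometric mean:** fixed-point iteration, tolerance 10⁻⁸ on the
  tangent-update Frobenius norm, at most 500 iterations, step halved
  whenever the update norm increases; non-convergence is an error, not
  a silent result.  Matrix log/sqrt use symmetric eigendecompositions
  with a 10⁻¹² relative eigenvalue floor that errors rather than clamps,
  so invalid covariances surface.
* **sLORETA:** default $\alpha = 10^{-2}\,\mathrm{tr}(KK^\top)/E$ for
  noisy data; localization tests use $10^{-8}$.  Rank-deficient
  standardization blocks are an error by default with an opt-in
  pseudo-inverse mode.
* **Balancing:** per subject (never pooled), removing only
  majority-class trials, preserving within-class order, seeded.
* **CSP** (comparison baseline): generalized eigenvectors of the
  class-0 mean covariance against the pooled mean, paired
  largest/smallest components, log-variance features.

## Problem sizes used by the test suite

Unit tests run on toy instances (2–6 channels, tens of trials).  The
multi-seed ordering studies in the acceptance tests use 5 subjects,
24/48 trials per class at 128 Hz over 10 generator seeds, with a
12-permutation label-shuffled null — sizes chosen so the full suite
completes in a few minutes while leaving the orderings unambiguous.
The generator defaults remain the full 15-subject design.

## Limitations

* Synthetic data only is exercised; the optional entry points for real
  epoched recordings (`epoch_set()` from your own arrays,
  `lead_field()` from a real forward solution) are interfaces, not
  validated pipelines.
* The sLORETA stage assumes an accurate lead field; with the average
  head models used in practice, inter-subject source-space decoding is
  known to degrade, and the package makes no attempt to model that.
* No artifact simulation or rejection (eye movements, ICA) — those
  belong upstream of this package.
* The comparison suite's statistics are the single pairwise
  Mann–Whitney tests; no multiplicity correction is applied.
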