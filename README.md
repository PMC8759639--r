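# riemerp

Single-trial classification of event-related EEG potentials with xDAWN
spatial filtering and Riemannian geometry of covariance matrices.

## What it does, and for whom

Event-related potentials (ERPs) are classically analysed by grand
averaging, which hides everything trial- and subject-specific.  This
package takes the opposite route, standard in the brain–computer
interface field: classify *single* 500-ms EEG epochs.  It is aimed at
EEG/ERP researchers who want a tested, self-contained implementation of
the covariance-based decoding stack:

* **xDAWN spatial filters** — per class `k`, the filters `w` maximizing
  the generalized Rayleigh quotient
  `w'P⁽ᵏ⁾P⁽ᵏ⁾'w / w'XX'w` (evoked energy over total signal energy),
  obtained from the generalized eigenproblem on `(P⁽ᵏ⁾P⁽ᵏ⁾', XX')`,
  keeping the `F` leading filters per class.
* **Augmented-trial covariances** — each trial `Xᵢ` becomes the
  `4F × 4F` covariance of `Z̃ᵢ = [W₀'P⁽⁰⁾; W₁'P⁽¹⁾; W'Xᵢ]`, estimated
  with OAS or Ledoit–Wolf shrinkage (`F = 3` with 12 electrodes gives
  12 × 12 matrices).
* **Tangent-space mapping** — covariances are projected at the
  geometric (Fréchet/Karcher) mean `Σ_ref` of the training set,
  `Φ(Σ) = Σ_ref^{1/2} log(Σ_ref^{-1/2} Σ Σ_ref^{-1/2}) Σ_ref^{1/2}`,
  then isometrically half-vectorized (off-diagonals × √2) into
  `n(n+1)/2`-dimensional features.
* **Ridge logistic regression** on the tangent vectors.
* **sLORETA** — the standardized minimum-norm inverse
  `T(α) = K'(KK' + αI)⁻¹` with per-voxel standardization by the 3 × 3
  resolution-matrix blocks, plus atlas-style region averaging, so the
  identical pipeline runs on cortical source activations.
* **Evaluation harnesses** — leave-one-subject-out (inter-subject) and
  per-subject stratified 4-fold (intra-subject) cross-validation;
  accuracy, MCC, ROC/AUC, precision–recall/AP, Mann–Whitney comparisons
  of fold accuracies; a six-pipeline comparison suite (vectorized LR,
  covariance+LR, covariance+TS+LR, xDAWN-covariance+LR, CSP+LR,
  xDAWN-covariance+TS+LR); greedy forward electrode selection and
  scalp-region triad analysis.
* **A synthetic multi-subject ERP generator** (class-specific P100 /
  biphasic / P220 morphology, occipitally dominant topography, 1/f
  background noise, per-subject gain/mixing/latency variability) so the
  whole stack is testable without any recordings, plus a source-space
  variant with ground-truth active voxels.

## Worked example

```r
library(riemerp)

## simulate a 5-subject study (24 vs 48 trials per class, 128 Hz)
cfg <- sim_config(n_subjects = 5, trials_per_class = c(24, 48),
                  sampling_rate = 128)
epochs <- simulate_epochs(cfg, seed = 1)

## condition the signals the classical way
epochs <- bandpass_filter(epochs, 1, 45)   # zero-phase Butterworth
epochs <- baseline_correct(epochs)         # subtract pre-stimulus mean
epochs <- crop_epochs(epochs, 0, 0.5)      # keep [0, 500) ms
epochs <- balance_classes(epochs, seed = 1)
epochs
#> <epoch_set> 240 trials x 12 channels x 64 samples @ 128 Hz
#>   time span: [0.000, 0.500) s relative to stimulus
#>   classes: 120 / 120 (0/1); subjects: 5

## the main pipeline: xDAWN -> covariance -> tangent space -> LR
spec <- pipeline_spec("xdawn_cov_ts_lr", n_filters = 3)

inter <- run_loso(epochs, spec)                         # inter-subject
inter
#> <cv_report> xdawn_cov_ts_lr | loso | 5 folds
#>   accuracy 0.662 +/- 0.232 | MCC 0.329 | AUC 0.730 | AP 0.708

intra <- run_kfold_per_subject(epochs, spec, k = 4, seed = 1)
intra
#> <cv_report> xdawn_cov_ts_lr | kfold | 20 folds
#>   accuracy 0.979 +/- 0.046 | MCC 0.959 | AUC 0.997 | AP 0.997

compare_accuracy_distributions(intra, inter)$p
#> [1] 0.000266
```

Reading the numbers: decoding a *held-out subject* succeeds well above
the 0.5 chance level (0.662 mean over 5 LOSO folds), but decoding
held-out trials of a *known* subject is far easier (0.979 over 20
subject × fold accuracies) — the central inter- vs intra-subject
contrast of single-trial ERP work, here significant by a Mann–Whitney
test on fold accuracies (p ≈ 3 × 10⁻⁴).  Per-fold predictions, pooled
confusion matrices and ROC/PR curves live inside the `cv_report`
objects; `write_report()` serializes them to JSON.

`run_comparison_suite()` reproduces the six-pipeline ranking table,
`forward_electrode_selection()` and `region_triad_analysis()` the
electrode-count and scalp-region analyses, and
`simulate_source_epochs()` + `project_to_regions()` the source-space
variant.  See the vignette in `vignettes/` for the model details and
every numerical convention.

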