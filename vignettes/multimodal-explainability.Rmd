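---
title: "Methods: modality-level explanations for multimodal sleep-stage classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modality-level explanations for multimodal sleep-stage classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the methods implemented in **modex**: the
classifier, the two families of explanation methods (ablation and
layer-wise relevance propagation), the covariate regression of local
explanation magnitudes, and the synthetic data generator used to validate
all of them. Code chunks are shown but not evaluated here; every numerical
claim in this document is a property checked by the package's test suite
or computed by `scripts/acceptance.R`.

## Scientific problem

Automatic sleep staging assigns one of five stages (Awake, NREM1, NREM2,
NREM3, REM) to each 30-second epoch of a polysomnography recording. A
multimodal classifier consumes three simultaneously recorded signals —
EEG, EOG (eye movements), and EMG (chin muscle tone) — sampled at 100 Hz,
so each sample is a 3000 × 3 matrix. The question the package addresses is
not *whether* such a classifier works but *which modality it relies on*,
per classification group (true stage, predicted stage): a model that
stages sleep from EMG alone behaves very differently under electrode
failure than one that uses EEG, and modality reliance that varies with
age, sex, or medication is a fairness and robustness concern.

## The classifier

`build_cnn()` constructs a 1-D convolutional network operating on the raw
3000 × 3 epoch:

* four blocks of two valid (no padding) convolutions with ReLU; kernel
  length 5 in the first block, 3 afterwards; each of the first three
  blocks ends in max-pooling of size 2, the fourth in global max pooling;
* two dense ReLU layers, then a dense softmax layer over the five stages;
* dropout after each block and dense layer (rates 0.01 to 0.1) during
  training only.

The default filter widths are 16/32/32/256 with dense widths 64/64; the
tests and the acceptance script use reduced widths (for example 8/8/8/32
with dense 32/32), which preserves the architecture while keeping CPU
training inside a few minutes. With the default input length of 3000 the
temporal dimension evolves as 3000 → 2996 → 2992 → 1496 → 1494 → 1492 →
746 → 744 → 742 → 371 → 369 → 367 → 1 (global max pool).

Training (`train_fold()`) uses mini-batch gradient descent with Adam,
inverse-frequency class weights, a learning-rate drop by a factor of 10
after a stagnation plateau on validation accuracy, early stopping, and
checkpointing of the epoch with the best validation accuracy. Splits are
*subject-wise* (`make_folds()`): a subject's recordings are never divided
between train and test. At 22 subjects the split is 17 train / 2
validation / 3 test; other cohort sizes use the same proportions.

## Global ablation

`global_ablation()` measures modality importance at the group level. For
one modality at a time, the classifier is re-evaluated on the test set
with that modality's channel replaced by either

* zeros (`"zero"`), or
* a synthetic 50 Hz line-noise artifact (`"line_noise"`): a sinusoid of
  amplitude 0.1 plus Gaussian noise, parameterized by frequency,
  amplitude, noise standard deviation, and phase.

Importance is the **percent change in group count** (PCG): with $n$
samples in a (true, predicted) group before ablation and $n'$ after,

$$\mathrm{PCG} = 100\,(n' - n)/n.$$

Groups with $n = 0$ have undefined PCG and are reported as missing. At a
100 Hz sampling rate the 50 Hz line-noise sinusoid sits exactly at the
Nyquist limit: with phase $\pi/2$ and zero noise it degenerates to the
alternating sequence $+a, -a, +a, \dots$, which the test suite verifies
both point-wise and spectrally.

## Local ablation

`local_ablation()` applies the same signal replacement per sample, but
scores the change in the predicted probability of the sample's original
top class: $\mathrm{PCG} = 100\,(p' - p)/p$ with $p$ the unmodified and
$p'$ the modified top-class probability. Note the top class is fixed at
the unmodified prediction, so the score measures how much the evidence
for the *original* decision depends on the modality.
`local_to_global()` aggregates local scores to group level as the
per-fold mean of $|\mathrm{PCG}|$, then the median across folds.

## Layer-wise relevance propagation

`lrp_explain()` starts with relevance 1.0 on the pre-softmax logit of the
predicted class and propagates it backwards to the input. Two rules are
implemented (`relevance_rule()`):

* **ε-rule.** A unit with pre-activation $z_k = \sum_j a_j w_{jk} + b_k$
  redistributes its relevance $R_k$ as
  $R_{j \leftarrow k} = \dfrac{a_j w_{jk}}{z_k + \varepsilon\,
  \mathrm{sign}(z_k)} R_k$, with $\mathrm{sign}(0) = +1$ and a zero
  denominator propagating zero relevance. As $\varepsilon \to 0$ and when
  all biases vanish, relevance is conserved layer by layer.
* **αβ-rule** (with $\alpha - \beta = 1$, $\alpha, \beta \ge 0$).
  Positive and negative contributions are pooled separately,
  $R_{j \leftarrow k} = \left( \alpha \frac{(a_j w_{jk})^+}{P_k}
  - \beta \frac{(a_j w_{jk})^-}{N_k} \right) R_k$, where $P_k$ and $N_k$
  include the positive/negative part of the bias. For $(\alpha, \beta) =
  (1, 0)$ the propagated relevance is everywhere non-negative and, with
  zero biases, conserved.

Convolutions are handled as the affine maps they are (the tests verify
equality with an explicitly unrolled Toeplitz matrix), max-pooling routes
relevance winner-take-all (ties to the earliest position), and dropout
and flatten are pass-throughs. Correctness is established against a
brute-force *path-enumeration oracle*: on networks small enough to
enumerate every path from an input unit to the output, input relevance is
the sum over paths of the product of per-edge factors, and the package
implementation must agree to within $10^{-10}$.

`lrp_dataset()` reduces input relevance to one number per (sample,
modality) — the sum of absolute relevance over the modality's 3000 time
points — and `modality_percent_relevance()` pools these within (true,
predicted, fold) groups, converts to percentages of the group total, and
takes the median across folds. `relevance_time_course()` produces the
per-epoch percentage course through a night, optionally smoothed with a
moving average.

A numerical note: with a large stabilizer such as $\varepsilon = 100$ the
absolute relevance reaching the input after ~12 affine layers is of order
$10^{-16}$, because every layer divides by a stabilized denominator. This
is expected shrinkage, not underflow of meaning: the *percentages* within
a group are invariant to the common scale.

## Covariate analysis

`importance_covariate_analysis()` regresses per-sample explanation
magnitudes ($|\mathrm{PCG}|$ for ablation records, percent absolute
relevance for LRP records) on age, medication (temazepam = 1), and sex
(female = 1), jointly by ordinary least squares, in each of the 75
(modality, true stage, predicted stage) cells. Cells that are empty, have
constant predictors, or yield rank-deficient designs are reported with an
explicit `skipped` reason. Benjamini–Hochberg FDR control at 0.05 is
applied separately to each (variable, modality) family of 25 group
p-values. When a sample occurs in several folds, only its first fold
enters the regression.

The test suite checks both directions: a planted sex effect in a single
cell must be recovered with the correct sign and survive FDR, and with
covariates shuffled across subjects the fraction of families with any
discovery must sit near the nominal 0.05 (under independent null
p-values, the step-up procedure's family-wise any-rejection probability
equals α exactly).

## Synthetic data generator: scope

`synth_dataset()` generates multimodal recordings whose ground truth is
known by construction, which is what makes the explanation methods
testable:

* each stage plants a band-limited oscillation (2/6/10/16/22 Hz for the
  five stages) into **one designated modality**; the other channels carry
  only noise (and, optionally, a weak stage-independent background
  rhythm);
* covariates modulate the planted amplitude multiplicatively (sex,
  medication) or linearly in age, so that covariate effects on
  explanations are also plantable;
* `write_sleep_edf_pair()` serializes a synthetic recording to an
  EDF/EDF+ file pair in the telemetry naming scheme (`ST7ssNJ*-PSG.edf` +
  hypnogram), which exercises the same ingest path
  (`read_sleep_edf_dir()` → epoching, stage-4 merging into NREM3,
  error-marker exclusion, z-scoring) that real recordings would take.

The generator is deliberately *not* a physiological simulator: stages
cycle deterministically, spectra are single-band, and stage-transition
structure is absent. Its purpose is planted-truth validation, not realism.

## Limitations

* **Count-based PCG is coarse.** Global PCG moves only when
  classifications cross group boundaries; with a dominant "dump" class,
  ablating an uninformative modality can *increase* some diagonal counts,
  so unsigned magnitude, not sign, should be compared across modalities.
* **LRP assumes the implemented layer set.** The propagation rules cover
  exactly the layers of this architecture; attention, normalization, or
  residual connections would need additional rules.
* **Offline validation only.** All validation in this package runs on
  synthetic data with planted truth. Properties that require the original
  telemetry recordings (for example reproducing a published dataset's
  exact composition) can only be checked for machinery, not for values,
  and are exercised here on synthetic EDF pairs.
* **OLS on bounded responses.** Percent relevance is bounded; the
  regression is a screening tool under FDR control, not a calibrated
  effect-size model.

## Reproducing the computed quantities

```{r, eval = FALSE}
# full test suite (installed package)
testthat::test_dir("tests/testthat", package = "modex",
                   load_package = "installed")

# acceptance run: writes the main quantities to JSON
# Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```
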