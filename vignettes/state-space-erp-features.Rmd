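---
title: "State-space identification features for ERP classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-space identification features for ERP classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpssid)
```

## The problem

An averaged event-related potential (ERP) is the stimulus-locked mean of
many EEG epochs: a smooth, decaying, oscillatory deflection that follows a
discrete stimulus. In a Go/NoGo task the two trial types produce averaged
waveforms that differ subtly in amplitude and latency (most prominently in
the N2 component, 200–350 ms post-stimulus), and a natural machine-learning
question is whether a classifier can tell the two conditions apart from the
waveforms alone.

Classifying raw waveforms is a high-dimensional problem: 62 electrodes
times 471 samples is 29,202 numbers per subject. `erpssid` implements a
model-based dimensionality reduction: each electrode's waveform is treated
as the *impulse response* of a continuous-time linear system — the stimulus
is the impulse, the brain's measured voltage response is the output — and
the fitted system's transfer-function coefficients replace the samples.
An order-`nx` single-input single-output model

$$\dot x(t) = A x(t) + B u(t), \qquad y(t) = C x(t)$$

has impulse response $g(t) = C e^{At} B$ and transfer function

$$H(s) = C (sI - A)^{-1} B
       = \frac{\beta_{nx} s^{nx-1} + \cdots + \beta_1}
              {s^{nx} + \alpha_{nx} s^{nx-1} + \cdots + \alpha_1},$$

which is fully described by $2 nx$ coefficients — 40 numbers per electrode
at $nx = 20$ instead of 250–471 samples. Since identified models can be
complex-valued (see below), each coefficient is split into real and
imaginary parts, giving $4 \times 20 \times 62 = 4960$ features, an 83%
reduction relative to the full raw matrix.

## The realization algorithm

Identification proceeds by Kung's classical realization method
(`build_hankel()`, `factor_hankel()`, `realize()`):

1. Arrange the samples into a Hankel matrix $G[r, c] = g(r + c)$. For a
   noiseless order-`nx` system, $\operatorname{rank} G = nx$.
2. Factor $G$ by SVD into the observability and controllability factors
   $O_c = U_1 S_1^{1/2}$, $C_c = S_1^{1/2} V_1^T$ at the chosen rank.
3. The row-shift structure of $O_c$ gives the sampled transition matrix
   $e^{A \Delta T} = O_{c1}^{\dagger} O_{c2}$; the continuous-time state
   matrix is its principal matrix logarithm divided by $\Delta T$, and
   $B, C$ are read off the first column/row of the factors.

The matrix logarithm is where complex numbers enter: when the estimated
discrete transition matrix has eigenvalues on the closed negative real axis
(which noisy data produce routinely), the principal logarithm is complex,
and the model — and its transfer-function coefficients — are retained as
complex quantities rather than rejected. This is exactly why the feature
layout reserves an imaginary slot for every coefficient.

Numerical choices: the pseudoinverse $O_{c1}^{\dagger}$ uses SVD least
squares with a relative cutoff of $10^{-12} s_{\max}$; the matrix
exponential uses scaling-and-squaring; the logarithm uses an
eigendecomposition and rejects matrices whose eigenbasis reconstruction
error exceeds $10^{-6}$ (near-defective cases). Characteristic polynomials
in `ss2tf()` are expanded from eigenvalues (root products), which remains
well conditioned at the orders (~20) used here. The Hankel matrix defaults
to the near-square shape $i = \lceil (N+1)/2 \rceil$, $j = N - i + 1$,
using all samples and maximizing usable rank.

## Model-order selection

The model order is unknown. On clean data the singular-value spectrum of
$G$ cuts off sharply at the true order (`estimate_order()` counts values
above a $10^{-6}$ relative threshold); on noisy data the spectrum decays
gradually and a fitting-error criterion governs instead.
`fit_optimal_order()` increases the candidate order one step at a time,
realizing a model and scoring it by the mean squared error

$$f = \frac{1}{N} \sum_{t=0}^{N-1} \big(g(t) - g_{\text{fit}}(t)\big)^2,$$

and stops when improvements dry up. Two details matter:

* **Patience.** Stable oscillatory systems carry poles in conjugate pairs,
  so an odd-order candidate sandwiched between two even orders often shows
  no improvement at all. Stopping at the first flat step would
  systematically underfit by one pair; the search therefore tolerates 2
  consecutive non-improving orders (`patience = 2`) before stopping, with
  improvement always measured against the best error so far.
* **Improvement threshold.** Raising the order by one adds two free
  parameters, which absorb roughly $2/N$ of the residual even from pure
  noise. The default threshold is therefore $\max(10^{-3}, 4/N)$ — about
  twice the chance-level gain — so the search does not creep up the order
  ladder fitting noise. With 250-sample windows this is 1.6%.

For averaged ERP recordings the spectrum typically cuts off between orders
17 and 21, and a search may start directly at `n_min = 17` (the default of
`fit_optimal_order()`). For signals of unknown complexity — including the
synthetic data below — the search should start at `n_min = 1` and climb,
which is what the featurization pipeline does by default.

## One common order for the whole dataset

`build_feature_matrix()` does **not** simply give every signal its own
MSE-optimal order. Polynomial coefficients are symmetric functions of
*all* model poles: two fits of the same electrode that happen to settle on
orders 4 and 6 differ not by two extra slots but in every coefficient, by
factors on the scale of the extra poles' magnitudes. Columns built from
mixed-order fits are therefore incomparable across signals, and extra
noise-fitting poles randomize the coefficients multiplicatively. (This is
measurable: with per-signal orders the end-to-end synthetic classification
below sits at chance; with one common order it is nearly perfect.)

The default pipeline settles a single order for the whole recording in two
stages: a pilot round runs the full order search on a stratified subsample
of 32 signals across all electrodes; each pilot trace contributes its most
*parsimonious* near-optimal order (the smallest order whose MSE is within
5% of the trace minimum — robust against the noise-driven tail of the
trace); and the mode of those orders becomes the common fitting order. All
signals and electrodes are then fit at that order, and the coefficients
are padded into the fixed `target_order = 20` feature frame. Zero-padding
goes at the high-degree end so constant-term coefficients stay aligned;
orders above the target are truncated from the high-degree end. Explicit
control is available: `common_order = <integer>` fixes the order directly,
`common_order = NULL` restores fully per-signal orders.

## The evaluation harness

`pca_scores()` projects the feature matrix onto its leading principal
components; classification uses six standard algorithms (KNN, Gaussian
Naive Bayes, decision tree, LDA, linear-kernel SVM, random forest — all
standard implementations from `class`, `e1071`, `rpart`, `MASS`,
`randomForest`) under stratified 5-fold cross-validation
(`run_algorithms()`, `sweep_pcs()`, `knn_grid()`). Metrics are the six
confusion-matrix scores ACC, ERR, PRE, SEN, SPE, F1; zero-denominator
cases return 0 with a warning. Reported "accuracy" is the mean of per-fold
accuracies; metric reports use the confusion counts pooled over folds
(with equal fold sizes the two accuracies coincide).

Two deliberately exposed switches:

* `pca_per_fold` (default `TRUE`): PCA is fit inside each training fold
  and the test fold is projected onto it, so no test information leaks
  into the rotation. `FALSE` restores the simpler fit-once-on-all-data
  workflow for comparability with analyses that compute one score matrix
  up front.
* `pca_scale` (default `FALSE`): PCA runs on column-centered features. For
  transfer-function coefficients, however, column variances span tens of
  orders of magnitude (a degree-0 denominator coefficient is a product of
  all pole magnitudes), and unscaled PCA is dominated by a handful of
  extreme columns. The end-to-end examples therefore pass
  `pca_scale = TRUE`, standardizing columns (zero-variance columns pass
  through unscaled) before the decomposition. On the synthetic data this
  is the difference between chance and near-perfect accuracy.

The classifier hyperparameters are deliberately plain: KNN with Euclidean
distance and `k = 5` neighbors by default (the KNN grid sweeps `k`),
Gaussian NB, an unpruned-depth CART tree, linear-kernel SVM with cost 1,
and a 100-tree random forest. All cross-validation and classifier
randomness is derived deterministically from the `seed` argument.

## The synthetic generator

No public ERP dataset accompanies this pipeline, so `generate_dataset()`
produces a fully seeded surrogate with known ground truth, matching the
geometry of a two-condition study: 255 signals per class, 62 electrodes,
471 samples at 500 Hz (−140 to 800 ms, 70 baseline samples). Per
electrode, one stable state-space model of order 4 is drawn with damping
rates in −12 to −2 s⁻¹ and oscillation frequencies in 2–10 Hz (the band of
the dominant ERP components), scaled to a 10 µV peak. The "Go" class uses
the model as is; the "NoGo" class scales dampings by $1 - \epsilon$ and
frequencies by $1 + \epsilon$ with `class_effect` $\epsilon = 0.15$ —
placing the class difference in the *dynamics*, the quantity the
transfer-function features measure, as a stand-in for the N2
amplitude/latency differences between conditions. Every signal is its
class's clean response plus white Gaussian noise with standard deviation
5% of the peak (≈ the residual noise level of a few-hundred-trial
average); baseline samples are noise-only.

What the generator does *not* emulate: inter-subject variability in the
underlying dynamics (all signals of a class share one clean waveform per
electrode), volume conduction and inter-electrode correlation, artifacts
(eyeblinks, line noise), and the 1/f spectral shape of residual EEG noise.
Passing tests on this surrogate therefore demonstrate that the pipeline
recovers dynamics-encoded class structure under additive noise — not that
real Go/NoGo recordings would yield any particular accuracy. True model
order 4 (rather than ~20 as real averaged ERPs exhibit) keeps desk-scale
runs fast while still exercising the zero-padding path of the feature
layout; a high-order stress profile is one `generator_config(true_order =
20)` away.

## Problem sizes and runtime

The worked examples and the acceptance script run the full study geometry:
510 signals × 62 electrodes, identification on the 250-sample
post-stimulus window (samples 71–320, i.e. stimulus onset to +498 ms), a
510 × 4960 feature matrix, and cross-validated evaluation at component
counts up to 36. A complete run takes a few minutes on a single core; unit
tests use reduced sizes (tens of signals, orders ≤ 8) chosen to exercise
the same code paths.

## Degenerate inputs and edge cases

All-zero or constant signals have no defined model order and are rejected
by `estimate_order()` before any factorization. Candidate models whose
simulated response overflows (unstable noise modes) are scored with
infinite error and end the order search; if every candidate fails, the fit
fails, and `build_feature_matrix()` records the failure, zero-fills the
affected block, flags the row, and aborts only if more than 5% of fits
fail. A realized model's simulated response may carry a numerically tiny
imaginary residue; it is discarded after checking it stays below $10^{-6}$
of the real magnitude, with a warning otherwise.

## A short worked example

```{r example, eval = FALSE}
cfg <- generator_config(n_per_class = 30, seed = 1)
ds <- generate_dataset(cfg)
fm <- build_feature_matrix(ds, fit_config(window = c(71, 250)))
dim(fm$values)              # 60 x 4960
fm$common_order             # 4 on this generator

reports <- run_algorithms(fm$values, fm$labels, k = 5, seed = 1,
                          n_components = 3, pca_scale = TRUE)
sapply(reports, function(r) attr(r, "mean_accuracy"))
```

## Known limitations

* SISO only: one impulse-response channel per electrode; no multi-input or
  innovations-form (process-noise) identification.
* The realization step assumes a diagonalizable sampled transition matrix;
  truly defective systems (repeated poles with nontrivial Jordan
  structure) are rejected rather than handled.
* Coefficient features inherit the conditioning of high-order polynomials;
  the common-order procedure mitigates but does not remove this, and
  analyses at orders far above the data's true complexity will degrade.
* The evaluation harness is binary-classification only.
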