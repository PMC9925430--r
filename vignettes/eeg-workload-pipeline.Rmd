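---
title: "Classifying cognitive workload from multichannel EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cognitive workload from multichannel EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegworkload)
```

## The problem

Pilots (and operators generally) move between periods of low, medium and high
cognitive workload, and both extremes degrade performance. Scalp EEG carries
well-replicated workload signatures: frontal theta (4–8 Hz) power rises with
mental effort, parietal/occipital alpha (8–13 Hz) power falls, and
the beta-based engagement index tracks alertness. `eegworkload` implements a
complete, testable pipeline from labeled multichannel EEG to a three-class
workload decision: synthetic data generation, preprocessing, spectral/entropy
feature extraction, feature selection, and a stacked ensemble classifier
evaluated with macro-averaged, cross-validated metrics.

The montage is the 20-electrode international 10–20 layout (Fp1 … O2,
including POz) sampled at 256 Hz. Each analysis unit is one *maneuver
segment*: a 120 s window from maneuver onset, exactly 30,720 samples at
256 Hz. Shorter maneuvers are rejected rather than padded so that every
feature is computed from the same amount of data.

## Feature model

Per segment and channel, the power spectral density is estimated by Welch's
method: 1 s Hamming windows, 50 % overlap, per-window mean removal,
one-sided density scaling. A 1 s window at 256 Hz gives exactly 1 Hz
resolution, which makes band-edge bookkeeping exact: bands are half-open
intervals — delta [1, 4), theta [4, 8), alpha [8, 13), beta [13, 30] — with
beta's upper edge inclusive, so no PSD bin is counted twice. Band power is
the arithmetic mean of the density bins inside the band.

The full feature vector has 228 named entries on the 20-electrode montage:

| block | count | definition |
|---|---|---|
| `psd:<band>:<electrode>` | 80 | mean band density, 20 electrodes × 4 bands |
| `ratio:thetaF_alphaP:<f>:<p>` | 28 | frontal theta / posterior alpha, 7 × 4 pairs |
| `ratio:engagement:<e>` | 20 | beta / (alpha + theta) per electrode |
| `ratio:theta_beta:<e>` | 20 | theta / beta per electrode |
| `lee:<band>:<electrode>` | 80 | log energy entropy per band and electrode |

The theta/alpha ratio numerators are the seven frontal electrodes (Fp1, Fp2,
F7, F3, Fz, F4, F8). The denominator set must contain exactly four
electrodes for the block to have 28 entries; we use P3, Pz, P4 and POz — the
parietal row plus the parieto-occipital midline. O1/O2 are excluded: with
the parietal row present, four denominators are already fixed and the choice
keeps the set hemispherically balanced.

Log energy entropy is `E = sum_n log(w_n^2)` over a band representation of
the channel, with `w_n^2` floored at a configurable `eps` (default 1e-12)
because the sum is undefined at exact zeros. The natural logarithm is used;
the base only rescales every entropy feature by a shared constant, which
standardization removes, so it cannot change selection or classification.
Two backends define the coefficients `w_n`:

* **bandpass** (default): the zero-phase band-filtered time samples. This is
  unambiguous, cheap, and reproducible.
* **wavelet**: Daubechies-4 wavelet-packet node coefficients at depth 5
  (node width 4 Hz at 256 Hz), taking the union of nodes whose frequency
  interval centre lies inside the band. Provided for sensitivity analysis;
  a packet node grid cannot match the 1–4/13–30 Hz edges exactly, which is
  why it is not the default.

Column order is canonical and bit-exact across runs: the five blocks in the
order above, ordered inside each block by band (delta, theta, alpha, beta)
then electrode in montage order, ratio pairs frontal-major.

## Preprocessing

The cleaning front-end is deliberately simple and fully algorithmic:

* **Bandpass 1–45 Hz**, zero-phase. Implemented as a cascade of a 2nd-order
  Butterworth high-pass at 1 Hz and a 4th-order low-pass at 45 Hz, each run
  forward–backward. A single 8-pole bandpass with a normalized low edge of
  1/128 is numerically fragile in transfer-function form; the cascade meets
  the same contract (< 1 dB in-band ripple, > 20 dB at 0.25 Hz and 60 Hz
  after the double pass). Zero phase matters because features are spectral
  and group delay would misalign maneuver windows.
* **Bad channels**: dead channels are flagged by a robust SD below
  `flat_threshold` (default 0.1 µV); noisy channels by a robust z-score
  above `z_threshold` (default 5) of the log *median-window* variance
  across channels. The median over 1 s windows makes the criterion
  sensitive to persistent noise while ignoring sparse transients such as
  blinks, which are a different stage's job.
* **Spherical-spline interpolation** of up to two flagged channels
  (stiffness order m = 4, Legendre series truncated at 7 terms, ridge
  1e-5), using idealized unit-sphere 10–20 coordinates from a built-in
  table. Interpolation needs only relative geometry. Beyond two bad
  channels the call fails loudly instead of fabricating data.
* **Artifact windows**: a 1 s window is rejected when any channel exceeds
  150 µV peak absolute amplitude. This amplitude rule replaces interactive
  inspection and subspace-reconstruction cleaning; component-based (ICA)
  artifact removal is out of scope, so the pipeline's contract is "clean
  segments in, features out" with ground-truth artifact locations available
  from the simulator for testing.

Re-referencing is intentionally skipped: with 20 unevenly distributed
electrodes an average reference is spatially biased.

## The synthetic generator

Because real flight EEG of this kind is not publicly deposited, the
generator is a first-class module: it produces data with exactly the
statistical structure the analysis assumes, so every downstream stage has a
ground truth. Each channel is

1. a 1/f background (exponent 1.0, broadband RMS 10 µV), plus
2. one band-limited Gaussian component per band (brick-wall filtered white
   noise, rescaled to a target RMS), with amplitude = baseline band RMS ×
   gain(region, band, class), plus
3. artifacts: 400 ms raised-cosine blinks (80 µV at Fp1/Fp2, decaying ×0.2
   per step toward the back, default 8/min), optional line noise and dead
   channels.

Oscillations are filtered noise rather than sinusoids so the Welch
estimator faces realistic variance and leakage. Default class gains encode
the workload signature with tens-of-percent amplitude steps, the magnitude
range workload studies typically report: frontal theta (0.80, 1.00, 1.25)
for (low, medium, high), posterior alpha (1.30, 1.00, 0.75), beta everywhere
(0.90, 1.00, 1.15); baseline band RMS delta 6, theta 5, alpha 6, beta 3 µV.
A per-subject lognormal gain (σ = 0.2) applied uniformly across channels
emulates inter-individual amplitude differences — note that uniform gain
cancels exactly in the ratio features, as it should.

What the simulator does **not** emulate: volume conduction and realistic
cross-channel covariance, ERP structure, non-stationarity within a segment,
muscle artifacts, electrode drift. Passing tests on synthetic data therefore
demonstrate that the pipeline recovers the class structure it assumes, not
that real flight EEG is this separable; published real-data accuracies are
not reproducible claims of this package.

## Selection and classification

Features are standardized (train-fold mean/SD; zero-variance columns map to
zeros with a warning). Two selectors are provided:

* **RFE** with a linear SVM (C = 1): each surviving feature is scored by the
  sum of squared weights over the pairwise (one-vs-one) class SVMs, and the
  weakest feature is removed until 15 remain. The pairwise decomposition is
  the one a multiclass linear SVC actually fits, and it matters here:
  a "medium-vs-rest" problem is not linearly separable when the class
  effect is ordered, so a one-vs-rest criterion underweights genuinely
  informative features. Ties break toward the earlier (canonical) column.
* **LassoCV** on the ordinal-encoded label (low = 0, medium = 1, high = 2;
  workload is ordered, and a regression lasso on an encoded target is the
  standard "LassoCV" construction): squared-error lasso along a geometric
  grid of 150 λ values spanning [0.001·λmax, λmax], best λ by 10-fold CV
  MSE, fitted with glmnet coordinate descent (maxit 1500, tolerance 1e-4).
  Selection takes nonzero coefficients at the best λ ordered by |β|,
  padding from denser path points when fewer than 15 are nonzero.

The default subset size is 15; `sweep_subset_sizes()` reproduces the
size-selection experiment over {5, 10, 15, 20, 30, 40}.

The classifier is a two-level stack. Level 1: RBF SVM (C = 1, γ = 0.01),
random forest (500 trees), multinomial logistic regression (L2 weight
decay, tolerance 1e-4). Level 2: a random forest with the same
hyperparameters as the level-1 forest. The meta-features are *out-of-fold*
class-probability vectors (3 per learner, 9 columns) from an internal
5-fold over the training rows — in-sample level-1 predictions would let the
meta-learner fit their optimism. After the meta-model is trained, level-1
learners are refit on all training rows for prediction time.

Two ecosystem notes, recorded as deliberate deviations: R's random forest
splits on the Gini criterion (no entropy option); with 500 trees on 15
features the split criterion is not expected to matter. The logistic fit
uses `nnet::multinom` (BFGS with weight decay) rather than a
Newton-conjugate-gradient solver; both optimize the same penalized
multinomial likelihood.

Evaluation is stratified 10-fold cross-validation. Within each fold the
standardizer and (by default) the selector are fit on the training rows
only — `selection$mode = "global"` reproduces the selection-outside-CV
workflow for comparability, at the cost of a known optimistic bias.
Metrics are macro-averaged: per-class one-vs-rest precision, recall and F
(harmonic mean before averaging; zero-denominator metrics defined as 0 with
a warning), plain multiclass accuracy as the primary accuracy (the
one-vs-rest macro accuracy is also reported, since the binary accuracy
formula is ambiguous for three classes), and one-vs-rest ROC-AUC via the
midrank statistic (identical to trapezoidal ROC integration), unweighted
mean over classes. Fold assignment is seeded and recorded. Subject-grouped
folds are available (`groups =`) because pooling a subject's segments
across folds risks identity leakage; the default is segment-wise folds.

## Numerical choices and degenerate inputs

* PSD is density-scaled; ratio features are invariant to this choice.
* Ratio denominators are floored at machine epsilon, with a warning, so a
  pathological all-zero band cannot produce Inf.
* `log_energy_entropy` floors squared coefficients at `eps`; with the
  default 1e-12 the zero signal gives N·log(1e-12) rather than -Inf.
* RFE ties and lasso |β| ties break by canonical column order, so column
  permutations cannot change the selected feature *names*.
* Prediction ties go to the lexicographically first class label.
* glmnet's active-set coordinate descent can transiently drop a feature as
  λ decreases, so the nonzero count along the path is tested as
  non-decreasing up to a small fraction of adjacent pairs (< 5 %), not as a
  strict monotone.

## Problem sizes used by the test-suite and acceptance script

The default synthetic study is 10 subjects × 3 classes × 2 segments
(60 segments of 120 s), evaluated with 10-fold CV and fold-wise RFE to 15
features; selection-recovery experiments use 40 replicates of a 60 × 228
planted-signal design. These sizes give stable statistics while keeping a
full run in the minutes range on one core.

## Known limitations

* RFE keeps *a* sufficient subset, not every informative feature: with
  strongly collinear informative features and small n it may keep two of
  three redundant carriers. At the 60-row design used here, planted-signal
  recovery is complete across seeds.
* The amplitude-threshold artifact stage cannot remove artifacts that stay
  below threshold (it is a rejection rule, not a reconstruction).
* The EDF writer targets continuous equal-rate recordings with 1 s records;
  it is not a general EDF+ implementation.
* With 60 segments, 10-fold macro metrics have fold SDs of several points;
  single-fold numbers should not be over-read.
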