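---
title: "Population decoding of calcium-imaging responses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population decoding of calcium-imaging responses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popdecode)
```

# The analysis

`popdecode` implements a linear population-decoding analysis for two-photon
calcium imaging of mouse visual cortex. The pipeline asks how much information
about the visual stimulus — either one of six stimulus classes (drifting
gratings, static gratings, locally sparse noise, natural images, natural
movies, spontaneous activity) or one of eight drifting-grating motion
directions — can be read out linearly from the joint activity of a neural
population, how that readout scales with population size, and how much of it
depends on trial-to-trial noise correlations between neurons.

The stages are:

1. **Preprocessing.** Raw fluorescence is converted to
   $\Delta F/F = (F - F_0)/F_0$ per frame, with $F_0$ the mean fluorescence of
   the preceding 1 s. Stimulus-class epochs are divided into 10-s intervals
   (a trailing interval shorter than 10 s is discarded); grating trials
   contribute their 2-s presentation window, with the following 1-s gray
   discarded. Each interval or trial becomes one sample: the per-neuron mean
   $\Delta F/F$ over its window. For the class task, only neurons imaged in
   all three sessions are used, and samples from the sessions are pooled.
   Per-neuron features are z-scored over all samples of a dataset.
2. **Decoding.** A linear support vector machine (SVM) or multinomial
   logistic regression (MLR), $\ell_2$-regularized with penalty
   $\lVert\theta\rVert^2 / 2C$, where $C$ is selected by nested
   cross-validation over the grid
   $\{10^{-2}, 10^{-1}, 1, 10, 10^2, 10^3, \infty\}$. The class task uses
   5-fold outer cross-validation with balanced training subsamples (an equal
   number per class, 80% of the smallest class) and unbalanced test folds;
   the direction task uses a single random 80/20 split.
3. **Scaling.** Random neuron subsamples of sizes $1, 2, 4, \ldots$ (10
   resamples per size, plus the full population evaluated once) are each
   decoded in full; the mean accuracies are fitted with the constrained
   generalized logistic
   $$\mathrm{accuracy}(n) = \frac{1 - c}{(1 + e^{-an})^b} + c, \qquad
     a \ge 0,\; b \in [0, 1],\; c \ge 0,$$
   whose floor parameter $c$ absorbs the chance level at small $n$ and whose
   limit is 1 as $n \to \infty$; the fit is then used to extrapolate accuracy
   to 128 neurons.
4. **Noise-correlation synergy.** A correlation-blind decoder is trained with
   the identical procedure on training data whose trials were permuted within
   class independently per neuron (destroying across-neuron co-fluctuations
   while preserving every per-neuron per-class marginal exactly) and tested
   on intact data. The joint-minus-blind accuracy difference, compared with a
   paired t test across replicate runs, measures the contribution of noise
   correlations: positive differences indicate a synergistic code.
5. **Selectivity.** Per neuron, responses to the 40 grating conditions
   (8 directions × 5 temporal frequencies, 15 repeats each) are averaged;
   the preferred condition is the argmax, and
   $$OSI = \frac{R_{pref} - R_{orth}}{R_{pref} + R_{orth}}, \qquad
     DSI = \frac{R_{pref} - R_{null}}{R_{pref} + R_{null}},$$
   with $R_{orth}$ the mean response to the two directions orthogonal to the
   preferred one (at the preferred temporal frequency) and $R_{null}$ the
   response to the opposite direction. Because $\Delta F/F$ can be negative,
   both indices can be negative or exceed 1; values outside $[0, 2]$ are
   excluded from group averages (boundary values are kept).
6. **Statistics.** Tukey's honest-significant-difference test at family level
   0.05 for all-pairs comparisons of group accuracies; one-sided Welch t
   tests against a reference group with Holm adjustment; and the paired t
   test for joint-versus-blind comparisons.

# The synthetic-data generator

Since the original recordings are not redistributable, the package ships a
generator whose output has the statistical structure the analysis assumes.
Each simulated session is assembled from:

* **Calcium events.** Within stimulus-class epochs every neuron emits events
  as a Poisson process (default `eventRate = 0.5` Hz). One event is a
  transient with peak amplitude `classMeans[class, neuron]` × an
  exponential variate — the default mean peak of 2 (i.e. 200% $\Delta F/F$)
  is typical of strong somatic GCaMP6 transients — passed through a
  single-exponential calcium kernel (`calciumTau`, default 0.5 s).
* **Sustained grating responses.** During each 2-s grating trial a sustained
  response equal to the neuron's direction-tuning value (times a
  temporal-frequency gain) plus private Gaussian noise (`noiseSd`) is added;
  the 1-s gray gaps carry spontaneous background events only.
* **Direction tuning.** A two-lobed von Mises curve with exact constraints
  $r(\theta_p) = A$ and $r(\theta_p + 180^\circ) = d\,A$, so the
  direction-selectivity factor $d$ (`dsiFactor`) maps onto closed-form OSI
  and DSI values that the selectivity module must reproduce.
* **Noise correlations.** A single latent gain, redrawn every `blockS`
  seconds and shared by all neurons through per-neuron loadings, multiplies
  concurrent event and trial amplitudes. With `sharedGainSd = 0` neurons are
  conditionally independent; empirical pairwise noise correlation grows
  monotonically with `sharedGainSd`. A rank-1 structure is sufficient to
  produce both synergy and redundancy regimes and is easy to reason about.
* **Measurement.** $F = F_{base}(1 + \text{activity})$ plus white noise
  (`measurementSd`, default 1 a.u. on a baseline of 100).

`defaultSessionSpecs()` mirrors the three-session structure (gratings in A;
static gratings and natural images in B; noise in C; movies and spontaneous
everywhere) with equal total duration per class (1800 s), so that chance for
the 6-class task is exactly $1/6$. `balancedSessionSpecs(1000)` is the
compact, trial-free variant (600 samples) used for chance calibration. The
real sessions are *not* balanced; imbalance can be reproduced by passing a
custom `epoch_plan`.

## Why sparse events rather than stationary rate noise

The sliding-baseline $\Delta F/F$ is, to first order, a differencing filter
with zero gain at frequency zero. A consequence worth documenting: for *any*
stationary activity process, the mean $\Delta F/F$ over a 10-s interval
telescopes to terms concentrated at the interval boundaries, so the features
of adjacent intervals within one epoch share a boundary term with opposite
signs and are strongly anti-correlated (an MA(1)-like structure with lag-one
correlation near −0.5). A cross-validated classifier can exploit such
dependence between training and test samples, dragging label-independent
decoding *below* chance. Two design choices neutralize this:

* Large, sparse transients make the interval means dominated by the
  *nonlinear* part of the $F/F_0$ ratio (a transient is weighted more than
  its baseline rebound), which does not cancel and is independent across
  intervals — this is also how real calcium data escape the artifact.
* The outer cross-validation folds are stratified *and temporally contiguous
  within class* (each class's samples are cut into consecutive chunks), the
  fold construction of scikit-learn's `StratifiedKFold` without shuffling.
  Neighboring samples therefore share a fold, and the residual short-range
  dependence cannot leak between training and test data. The balanced
  training subsample within the training portion remains random.

## What the generator does not emulate

Movie- or noise-frame-locked temporal structure within epochs (classes are
distinguished only by their event-amplitude signatures), pupil/running
covariates, spiking statistics, retinotopy, and neuropil contamination are
out of scope. Passing chance-calibration and recovery tests on these
synthetics therefore shows that the *pipeline* is unbiased and correctly
implemented, not that it reproduces the quantitative accuracies attainable
on cortical data.

# Numerical and design choices

* **$\Delta F/F$ edge handling.** Frames earlier than one full baseline
  window use all available preceding frames; the very first frame has no
  baseline and is `NA`. Frames are assigned to segmentation windows by their
  temporal midpoints.
* **z-scoring** uses the population-SD convention (divide by $n$) and is
  applied once per dataset, before any train/test split. The mild leakage
  this creates is a property of the pipeline being reproduced, and is
  deliberate and documented.
* **Linear SVM.** The package implements the dual coordinate-descent solver
  for the L2-regularized L1-loss SVM (the liblinear algorithm, as used by
  scikit-learn's `LinearSVC`), in C++ with the standard shrinking heuristic,
  a regularized bias feature, tolerance $10^{-4}$ and a 1000-sweep cap.
  Multiclass problems use one-vs-rest with argmax over decision values.
  `e1071` (libsvm) serves as an independent cross-check in the test suite;
  its kernelized solver is impractically slow at large $C$ on weak-signal
  data of this size, which is why the decoder does not call it directly.
* **MLR** is `nnet::multinom` with weight decay $1/(2C)$, matching the
  $\lVert\theta\rVert^2/2C$ penalty.
* **$C = \infty$** is realized exactly for MLR (decay 0) and as
  $C = 10^6$ in the SVM dual, whose box constraint must be finite; at the
  z-scored feature scale the penalty is then numerically negligible.
* **Nested selection** uses 4 stratified inner folds within the first outer
  training set; the chosen $C$ is reused across outer folds. Accuracy ties
  are broken toward the smaller $C$ (stronger regularization). The reported
  accuracy pools the outer-fold confusion matrices
  (trace / total), so it equals the overall fraction correct; per-fold
  accuracies are retained alongside.
* **Curve fitting** is bounded nonlinear least squares: L-BFGS-B with
  analytic gradients from three starting points
  ($a \in \{0.1, 0.01, 1\}$, $b \in \{0.5, 0.9, 0.2\}$, $c$ from the smallest
  observed accuracy), keeping the best sum of squares; $c$ is additionally
  bounded above by 1 since accuracies live in $[0, 1]$. Line-search aborts
  are retried from the returned point. The full population size is appended
  to the power-of-two sizes and evaluated once (there is only one such
  subset).
* **Correlation-blind decoding** shuffles training data only; the intact
  test set is the common yardstick, so the blind decoder is penalized for
  ignoring real correlations. Ten independent shuffles are averaged per
  replicate, matching the subsampling repeat count.
* **Selectivity ties** (several conditions sharing the maximal mean
  response) go to the lowest direction, then the lowest temporal frequency.
  "Orthogonal directions" means both directions at ±90°, averaged. The
  exclusion rule keeps the closed interval $[0, 2]$.
* **Holm adjustment** is used for the one-sided t family (the adjustment
  method is otherwise unspecified in the analysis being reproduced; Holm is
  assumption-free), and Welch's unequal-variance t is used throughout.
* **Reproducibility.** Every stochastic operation takes an explicit seed;
  `runPipeline()` derives stage seeds from one configuration seed, and
  reruns are bit-identical.

# Problem sizes used by the test suite

The chance calibrations decode 64-neuron populations with 600 samples
(6-class task; `balancedSessionSpecs(1000)`) or 600 trials (direction task)
over 20 simulation seeds. Parameter-recovery checks fit sizes $1..128$;
type-I-error calibrations use 2000 null replicates. These sizes are the
package's own choices: large enough for the Monte-Carlo error of a 20-seed
mean (≈0.5 accuracy points) to sit well inside the ±2-point calibration
bands.

# Known limitations

* Single-trial accuracies from the generator saturate below 1 at small
  populations even for widely separated classes, because event-count
  (Poisson) and amplitude (exponential) variability put a floor on the
  per-sample noise; strongly decodable demonstrations use 16–64 neurons.
* A pure pairwise-correlation code (identical class means) is learnable by
  the hinge-loss SVM but provably not by logistic regression: with equal
  class means the logistic likelihood's population optimum is a constant
  predictor, while the hinge loss's non-strict convexity admits accurate
  solutions. Synergy analyses on equal-mean codes should therefore use the
  SVM decoder.
* The equal-duration default session plan idealizes the real (unbalanced)
  design so that the printed chance lines (16.67%, 12.5%) are exact.
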