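---
title: "Seizure detection from scalp EEG: methods and design notes"
author: "ictalEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seizure detection from scalp EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictalEEG)
```

## The problem and the model

Scalp EEG records the brain's electrical activity on (typically) 23
electrodes at 256 samples/s. During an epileptic seizure — the *ictal*
state — a subset of channels carries rhythmic, high-amplitude spike-wave
activity, so their amplitude variance rises sharply relative to the
interictal background. `ictalEEG` implements a classical machine-learning
pipeline that exploits exactly this signature:

1. **Epoching.** The record is cut into fixed-length windows (default
   10 s). An epoch is labelled *seizure* only when it lies entirely inside
   an annotated seizure interval, *normal* only when it lies entirely
   outside all of them. Epochs straddling a boundary are never used: the
   correct label of a half-ictal window is undefined, and discarding such
   windows avoids injecting label noise.
2. **Channel selection.** For each epoch, the population variance
   $V(c) = \frac{1}{K}\sum_{i=1}^{K}(X_c(i)-\mu_c)^2$ is computed per
   channel and the $k$ channels with the largest variance are kept
   (default $k = 3$, ties to the lower channel index). Three channels
   suffice for seizure detection; discarding the rest cuts the feature
   space from $11 \times 23$ to $11 \times 3$ values per epoch.
3. **Feature extraction.** Eleven features per selected channel: standard
   deviation (1/(N−1)), mean, maximum, minimum, variance (= STD²), median,
   skewness, amplitude-histogram Shannon entropy, kurtosis, fourth central
   moment and spectral power (see below).
4. **Averaging.** The $11 \times k$ values are collapsed to a single
   11-value row by the element-wise arithmetic mean, one row per epoch.
5. **Classification and validation.** Seven standard learners (SVM,
   bagged-tree ensemble, KNN, LDA, logistic regression, decision tree,
   Gaussian Naïve Bayes) are trained on z-scored rows and evaluated with
   stratified 5-fold cross-validation and the full confusion-matrix metric
   suite, with *seizure* as the positive class throughout.

## Feature conventions, and why they are what they are

Several of the textbook feature definitions admit more than one
convention. The ones fixed here are self-consistent and verifiable:

* **Spectral power** is `sum(F * Conj(F))` over the *unnormalised* DFT,
  so Parseval's theorem gives the exact identity
  $\mathrm{POW} = N\sum_i x_i^2$. Other FFT normalisations (1/N, 1/√N)
  would silently change POW by up to $N^2$; the identity is enforced by
  test at 1e−9 relative tolerance, so a substitution cannot go unnoticed.
* **Kurtosis** is the fourth standardised *population* moment, non-excess
  (a Gaussian signal gives 3). **Skewness** is the third standardised
  population moment; this is the standard definition (the symmetric
  counterpart of kurtosis), and values for EEG epochs land in the
  familiar −0.5…0.5 band.
* **Moment** is the central population moment of order 4 by default
  (configurable), which pins the exact identity
  $\mathrm{MOM} = \mathrm{KRT}\cdot\sigma_{pop}^4$ — also enforced by test.
* **STD** uses 1/(N−1) while the channel-selection variance uses 1/K.
  Both conventions are kept deliberately: the ranking in step 2 is
  invariant to the normalisation constant, so fidelity costs nothing, and
  `Var = STD^2` exactly within the feature vector. At $N = 2560$ samples
  the two conventions agree to far beyond printed precision anyway.
* **Entropy** is the Shannon entropy (natural log by default) of the
  per-epoch amplitude histogram with 100 equal-width bins spanning the
  epoch's range, normalised to a probability vector. Histogram entropy of
  a continuous amplitude has no canonical binning; 100 bins on a 2560
  sample epoch gives a stable estimate in the 4–5 nat range typical of
  scalp EEG. Bin count and log base are exposed as parameters. This is
  the one feature whose published values cannot be reproduced bit-for-bit
  from a definition alone; it is an explicit modelling choice here.

## Epoching protocols

Two testing protocols are supported.

**Continuous protocol** (`windowContinuous`): every annotated interval is
tiled into consecutive windows starting at the interval's onset, dropping
a partial trailing remainder — a 30-s event tiles into exactly three 10-s
epochs — and the non-annotated remainder of the record is tiled the same
way for the normal class. This mirrors evaluation on one patient's
consecutive record.

**Random protocol** (`windowRandom`): a seeded draw of `nPerClass` epochs
per class without overlap. Placements are sampled uniformly *from the
packed grid* of window-aligned starts inside each eligible segment.
This choice makes non-overlap structural rather than probabilistic, and
the per-class capacity is exactly
$\sum_{\text{segments}} \lfloor \text{len}/w \rfloor$, so an impossible
request fails early with the achievable count. Whether adjacent test
epochs may overlap was left open in the protocol's original description;
non-overlap was chosen (and is documented here as an assumption) because
overlapping test epochs share samples and would inflate the effective
test size.

## Classifiers

The original protocol names the seven learners but no hyperparameters.
Defaults follow common toolkit settings so results are reproducible and
honest about that silence: RBF-kernel SVM with $C = 1$; the ensemble is
bagging over CART trees (100 learners, all features per split — the
`randomForest` machinery with `mtry = p`); KNN with $k = 5$ (odd, so
binary votes cannot tie); LDA; logistic regression thresholded at 0.5;
CART with Gini impurity and no complexity pruning (`cp = 0`); Gaussian
Naïve Bayes. All are exposed through the `hyperparameters` argument.

Features are z-scored with training-set statistics inside
`trainClassifier` and the stored center/scale is re-applied at prediction
— never re-estimated — because the columns span ten orders of magnitude
(skewness ~0.1 versus spectral power ~1e12) and distance- or margin-based
learners would otherwise see only POW. One integer seed governs fold
assignment and every stochastic learner.

## Metrics

`computeMetrics` reports accuracy, sensitivity (= recall), specificity,
positive predictivity (= precision), F1, fall-out and miss rate, all on
the percent scale. Fall-out and miss rate are sometimes written as plain
ratios; here they are percentages like everything else, so
sensitivity + miss rate = 100 and specificity + fall-out = 100 hold
exactly. A metric with a zero denominator is reported as `NA` with a
warning — never silently as 0, which would fake a perfect or worthless
score depending on the metric.

## The abnormal-sample filter

Before training, a data-observation step can drop mislabelled "noise"
rows: `filterAbnormal` screens one designated feature (default `Mean`)
and removes a normal-labelled row lying more than `zThreshold` (default
3) robust standard deviations from the normal-class median *toward the
seizure class*, and symmetrically for seizure rows. Center and scale are
median and MAD per class; the screening direction comes from the sign of
the difference of class medians, so the rule is well defined whichever
way the feature separates. The original removal was a manual, visual
judgement on a scatter plot; this z-rule is this package's reproducible
operationalisation of it.

## The synthetic generator

`simulateRecord` emulates the statistical structure the pipeline assumes,
not scalp EEG physiology:

* **Background**: per-channel band-limited (1–30 Hz) colored noise with
  1/f amplitude weighting, standardised to `backgroundSd` (default 50 µV).
  Colored rather than white noise keeps the entropy and kurtosis features
  non-degenerate and the spectrum closer to real EEG.
* **Ictal bursts**: inside each annotated interval, the designated burst
  channels additionally carry a rhythmic spike-wave train (fundamental
  plus two harmonics, default 3 Hz) scaled to the RMS of a sinusoid of
  peak amplitude `amplitudeFactor × backgroundSd`, with a small seeded
  amplitude/phase jitter per interval. The expected ictal/interictal
  variance ratio on a burst channel is therefore
  $1 + \mathrm{factor}^2/2$ — 5.5 at the default factor 3 — which is what
  makes variance-based selection recover the burst channels.
* **Defaults** are the emulated recording conditions: 23 channels,
  256 samples/s, bursts on 3 channels, 40-s seizure events every 100 s
  (so a 10-s epoching yields roughly 40% ictal epochs, and both classes
  are populous).

`simulateFeatureTable` is a direct-to-feature shortcut for classifier
tests: one latent log-amplitude per row drives the amplitude family
(STD, Var, Max, |Min|, MOM, POW) so their natural algebraic couplings are
approximately preserved; seizure rows get a larger latent amplitude, a
right-shifted baseline offset and lower kurtosis, with all separations
proportional to `effect` — `effect = 0` yields literally one distribution
for both classes, so chance-level accuracy is the correct outcome. The
baseline offset (`Mean`) is drawn from a *truncated* Gaussian (±2.2 SD):
real baseline offsets are bounded after amplifier high-pass filtering,
and a bounded clean distribution is what makes "a clean table loses no
rows to the z = 3 filter" a property rather than a coin flip.

What the generator does **not** emulate: artifacts (EMG, eye blink,
electrode pop), inter-patient variability, non-stationary background,
sleep-stage effects, or realistic seizure morphology/propagation. Passing
tests on synthetic records therefore demonstrate that the pipeline's
machinery is correct and recovers planted structure; they do not certify
clinical accuracy on real recordings, which requires the clinical
database this package deliberately does not ship.

## Numerical and degenerate-input choices

* Zero-variance epochs: skewness and kurtosis are undefined; both return
  0 with a warning (not `NA`), so downstream tables stay numeric.
* Entropy of a constant signal is 0 (single occupied bin).
* Channel-selection ties break toward the lower channel index,
  deterministically.
* EDF storage is 16-bit; round trips are exact to within half a
  quantisation step (channel range / 65535), and the writer re-parses its
  own precision-limited header fields before encoding so that
  write-then-read is self-consistent.
* Fold assignment shuffles within class and deals round-robin with a
  running offset across classes, so fold sizes differ by at most one both
  globally and per class; `K = n` is handled as leave-one-out.
* All simulation, fold assignment and stochastic training is driven by
  explicit integer seeds, and seeded code restores the caller's RNG
  state.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run entirely on synthetic
data at deliberately desk-friendly sizes: unit tests use short low-rate
records (e.g. 4–8 channels at 32–64 Hz), while the end-to-end benchmark
uses five 23-channel, 256 Hz, 1000-s records (about 100 ten-second epochs
each, 40 ictal / 60 interictal) with amplitude factor 3, 5-fold
cross-validated with the ensemble, plus a seven-classifier chance-level
control at 100 rows per class over five seeds. These sizes give stable
statistics while keeping a full run in the low tens of seconds.

## A worked run

```{r example}
cfg <- synthConfig(nChannels = 8, fs = 128, durationS = 400,
                   burstChannels = c(2, 5, 7), amplitudeFactor = 3,
                   seed = 42)
rec <- simulateRecord(cfg)
rec

windows <- windowContinuous(rec, 10)
table(vapply(windows, windowLabel, character(1)))

ft <- buildFeatureTable(windows, k = 3)
cv <- crossValidate("ensemble", ft, K = 5, seed = 42)
cv
```

## Known limitations

* The entropy feature is definition-sensitive; comparisons across
  implementations must fix bins and log base.
* The ensemble's published description names neither base learner nor
  size; bagged CART with 100 trees is an assumption (configurable).
* Channel selection is recomputed per epoch (the per-record majority-vote
  variant `selectTopKMajority` is provided but is not the default); with
  very short epochs the per-epoch ranking is noisier.
* Absolute accuracies on real clinical recordings are out of scope here:
  the package reads EDF and can be pointed at such data, but ships no
  claims about it.
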