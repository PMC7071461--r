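---
title: "Welch band-moment EEG classification: models, parameters and design choices"
author: "eegmoments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Welch band-moment EEG classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmoments)
```

## The problem

Resting-state scalp EEG of patients with psychogenic nonepileptic
seizures (PNES) shows no visually evident abnormality, so epoch-level
machine-learning classification against healthy controls (CNT) is an
attractive aid for screening. `eegmoments` implements a complete,
reproducible version of such a pipeline: filtering and epoching of
multichannel recordings, Welch power-spectral-density (PSD) estimation,
band-wise statistical-moment features, and three classical classifiers
evaluated under *subject-level* validation. Because clinical EEG cannot
be redistributed, the package ships a synthetic cohort generator that
reproduces the geometry and the statistical structure the pipeline
relies on, so every stage is testable end to end.

## The signal path

A recording is a channels x samples matrix (19-channel 10/20 montage,
256 Hz after optional decimation from 512 Hz). Preprocessing applies,
in order:

1. integer-factor decimation to the working rate (filters are then
   designed at the final rate);
2. a 3rd-order Butterworth bandpass, 1–70 Hz, plus an IIR notch at
   50 Hz (Q = 30), both run forward–backward (`filtfilt`), so the
   effective magnitude response is the square of the single-pass
   response and the phase is zero — the standard choice for offline
   EEG, keeping epoch alignment interpretable;
3. removal of annotated artifact spans (annotations are an *input*;
   the package performs no automatic artifact detection). The clean
   segments are concatenated and their boundaries remembered;
4. segmentation into nonoverlapping 5-s epochs of 1280 samples,
   earliest first, at most 120 per subject, never straddling an
   artifact splice.

The acquisition-side 0.5 Hz high-pass of typical clinical hardware is
treated as provenance only; the analysis high-pass is 1 Hz.

## Welch band moments

Each epoch channel is reduced to a one-sided PSD by Welch's method:
256-sample segments, periodic Hamming taper, 50% overlap (hop 128), so
a 1280-sample epoch yields L = floor((1280-256)/128)+1 = 9 averaged
modified periodograms. The modified periodogram of segment $x_i$ is

$$P_{xx}(f_k) = \frac{1}{f_s\,M\,U}\Big|\sum_{n=0}^{M-1} x_i(n)\,\omega(n)\,e^{-j2\pi kn/M}\Big|^2,
\qquad U = \frac{1}{M}\sum_n \omega(n)^2,$$

doubled at non-DC/non-Nyquist bins (one-sided *density* convention:
integrating over frequency recovers the tapered signal's variance —
this is the convention the package's Parseval tests pin down; the
spectrum-vs-density choice cancels in all standardized moments and only
rescales means and SDs uniformly). Segments are not detrended; the 1 Hz
high-pass has already removed DC. With `nfft = 256` at 256 Hz the grid
spacing is 1 Hz and a one-sided spectrum has 129 bins.

The PSD map (channels x bins) is sliced into five half-open bands —
delta [1,4), theta [4,8), alpha [8,13), beta [13,32) and the whole band
[1,32) — so shared edges belong to the upper band exactly once and the
four rhythm bands exactly partition the whole band on the 1 Hz grid.
Within each channel x band submap row, four *population* moments are
taken over the PSD bin values: mean $m$, standard deviation $d$
(1/N denominator), Fisher–Pearson skewness $v$, and non-excess Pearson
kurtosis $k$ (Gaussian ≈ 3). When $d = 0$ (a constant submap row, e.g.
an all-zero test signal) the standardized moments are undefined and are
set to 0 by convention, so degenerate inputs never inject NaN into a
classifier. Features are laid out channel-major (channel, then band in
the order delta/theta/alpha/beta/whole, then moment m/d/v/k): 20 values
per channel, 380 per 19-channel epoch, 45,600 per 120-epoch subject.
Scale equivariance pins the conventions: scaling a signal by $c$ scales
$m$ and $d$ by $c^2$ exactly and leaves $v$ and $k$ unchanged.

## Classifiers and validation

Three classifiers consume the z-scored feature rows: an RBF-kernel SVM
($\psi(x,x')=e^{-\gamma\|x-x'\|^2}$ with $\gamma = 0.01$, cost $C = 1$;
`degree` and `coef0` are inert for this kernel and kept only as
provenance), linear discriminant analysis, and Gaussian naive Bayes.
The "Bayesian network" of the surrounding literature is implemented as
Gaussian naive Bayes: with continuous 380-dimensional features and no
specified structure-learning or discretization step, the naive Gaussian
model is the only well-defined reading, and result tables in that
literature label the classifier "NB".

Feature standardization is fitted on the training epochs only and
applied to the test epochs; columns constant in training map to zero on
both sides. It is on by default because an RBF kernel with
$\gamma = 0.01$ applied to raw PSD moments (which span orders of
magnitude) is numerically degenerate; a `scale = FALSE` switch
reproduces the unscaled reading.

Validation operates on whole subjects, never on epochs:

* **Random split (RS)**: 7 training subjects per class drawn uniformly
  without replacement (1,680 training epochs at the default geometry),
  the remaining 3+3 subjects (720 epochs) test.
* **Leave-one-subject-out (LOO)**: one fold per subject; the held-out
  subject's 120 epochs form the test set.

Every split is asserted leakage-free at run time. Metrics use PNES as
the positive class; per-split confusion counts, precision/recall/F1,
and ROC/AUC (trapezoidal, tied scores grouped into one step — equal to
the Mann–Whitney statistic) are aggregated as mean ± SD per classifier
x scheme. Single-class LOO test sets have no defined ROC; those AUC
entries are NA and excluded from the scheme mean. Scheme-level ROC
curves are vertically averaged on a common FPR grid.

### Calibration-neutral fitting

Leave-one-subject-out necessarily trains on imbalanced classes: the
held-out subject's class is one subject (120 epochs) short. With weak
class signal, an unweighted fit of any of the three classifiers drifts
toward the majority training class — which is always the *wrong* class
for the held-out subject, biasing null-data accuracy far below chance.
The package therefore fits all three classifiers calibration-neutral:
balanced class weights for the SVM, uniform priors for LDA, and
posterior rescaling to uniform priors for naive Bayes. For balanced
training sets (the 7+7 random split) this is inert.

## The synthetic cohort generator

Each channel is an independent sum of four band-limited Gaussian
noises (delta/theta/alpha/beta) and a $1/f^\alpha$ background
($\alpha = 1$ by default), built by Fourier masking/shaping of white
noise and normalized to unit expected variance, then scaled by the
profile's relative band powers. An optional 50 Hz sinusoid models mains
contamination. The default CNT profile (delta 2.0, theta 1.0, alpha
1.5, beta 0.8 relative power on a unit-power background) gives the
delta-weighted, alpha-prominent shape of eyes-closed resting EEG.
Because the band components are explicit, the generator needs a
`backgroundPower` parameter alongside the background exponent so that
band-to-background ratios are defined; it defaults to 1.

Per-subject variability is a single lognormal multiplicative factor
per component (4 bands + background) per subject, shared across
channels, with log-scale SD `subjectSd = 0.1` by default — modest
inter-subject power variability that makes epochs within a subject
correlated, and hence subject-level and epoch-level splitting genuinely
different, while keeping chance-level calibration interpretable. Class
effects are injected by multiplying one band's power (the packaged
cohort pairs use an alpha-power ratio; 2x by default, 1x for null
cohorts). No claim about PNES physiology is implied — no validated
spectral biomarker exists, and the effect direction/size are free
simulation parameters.

Determinism: the whole cohort is a pure function of (profiles, spec,
seed). Per-subject streams derive from the master seed by the fixed
rule `(seed + 104729 * subjectIndex) mod (2^31 - 1)`, so any subject
can be regenerated independently. Functions that consume randomness
directly (e.g. `synthesizeBandNoise`) use R's global RNG; seed with
`set.seed` for reproducibility.

What the generator does *not* emulate: spatial covariance between
channels (the features are strictly per-channel, so cross-channel
structure adds nothing to coverage), ERP/transient morphology, eye
blink or EMG artifacts, and nonstationarity within a recording.
Passing tests on synthetic cohorts therefore demonstrate the pipeline's
correctness and calibration, not clinical performance on real EEG.

## Numerical and design notes

* **Interval semantics**: artifact annotations are half-open
  `[start, end)` second intervals, merged to canonical form (merging is
  idempotent). Epoch windows are 0-based half-open sample ranges.
  Re-applying an annotation to an already-masked recording is
  ill-defined (the time axis has been compacted), so masking exposes
  its invariants as: merge is idempotent, and the empty annotation is
  the identity.
* **Welch geometry**: window length = nfft = 256 with 50% overlap
  reconciles "50% overlap on 1280 samples" with a 256-sample segment
  length; all values configurable through `welchConfig`.
* **EDF**: 16-bit physical/digital scaling, 1-s records; round trips
  are exact to one quantization step of each channel's physical range.
* **Runtime geometry in tests**: unit tests run on reduced cohorts
  (2–6 subjects, 2–4 channels, 4–20 epochs); the acceptance checks run
  the full 10+10 x 19 x 120 geometry once for the effect cohort and
  once for the null cohort.

## Known limitations

* The pipeline reproduces a *method*, not clinical results: with
  private clinical recordings unavailable, classifier scores on real
  PNES/CNT data are out of reach by construction.
* Under leave-one-subject-out on *null* data with subject-level power
  jitter, the RBF-SVM with $\gamma = 0.01$ operates in a regime where
  all kernel values are nearly constant and the decision collapses to
  its bias term; the resulting per-fold predictions are one-sided and
  systematically anti-correlated with the held-out subject's class
  ("anti-learning", a documented failure mode of margin classifiers
  under leave-one-cluster-out). Balanced class weights reduce but do
  not remove it, and an independent implementation of the same
  classifier reproduces it on identical features. LDA and naive Bayes
  are chance-calibrated in the same setting. Conclusions from
  small-cohort LOO SVM scores near chance should be drawn with care.
* The Gaussian naive Bayes reading of "BN" ignores any intended
  network-structure learning; no structure is specified for continuous
  PSD moments, so none is implemented.
* Hyperparameters are fixed, not tuned: the point of the package is a
  reproducible reference pipeline, and tuning against synthetic
  cohorts would be meaningless for real data.
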