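---
title: "Simulating and decoding error-related potentials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding error-related potentials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`errpsim` studies a practical question in brain-computer interfacing: can a
single-trial classifier for error-related potentials (ErrPs) be trained
entirely on *simulated* EEG subjects and still decode unseen subjects, so
that per-subject calibration sessions become unnecessary?  The package
provides the three ingredients needed to pose that question quantitatively:

1. a **forward model** (analytic three-shell spherical head) mapping
   dipolar cortical sources to scalp electrodes,
2. a **generative ERP model** of the error and correct conditions with
   controlled trial-to-trial and subject-to-subject variability plus a
   brown-noise background, and
3. the **decoding and evaluation pipeline**: windowed-mean features, a
   class-weighted RBF support vector machine with exhaustive hyperparameter
   search, and the statistics used to compare subject-specific,
   leave-one-subject-out (LOSO), and generic (simulation-pooled) decoders.

# The forward model

Scalp EEG is, to excellent approximation, a linear projection of dipolar
source activity.  The default head is three concentric spherical shells
(brain, skull, scalp) with radii 80/85/92 mm and conductivity ratio
1 : 1/80 : 1.  For each harmonic order the potential in each shell is
$A r^n + B r^{-(n+1)}$; matching potential and radial current density at
the interfaces and imposing an insulating outer boundary yields a small
linear system per order, whose solution gives the radial transfer
coefficients of the Legendre series.  Two numerical choices matter:

* **Rescaled unknowns.**  The raw per-order system mixes terms like $r^n$
  and $r^{-(n+2)}$ and becomes catastrophically ill-conditioned beyond
  order $\approx 50$.  The solver therefore rescales the unknowns so every
  matrix entry is a ratio of radii ($\le 1$) times $O(n)$; the solve is
  then stable to order 200 and beyond.  The test suite verifies the
  rescaled solver against the classic closed form for a homogeneous sphere
  and against an independently coded raw-matrix solve at moderate order.
* **Truncation and source depth.**  The series is truncated at 60 terms
  (configurable).  Convergence is governed by $(b/r_1)^n$ (source depth
  $b$, inner-skull radius $r_1$) and strongly accelerated by the skull's
  spatial low-pass; sources are sampled inside a 75 mm ball, where the
  60-term series agrees with a 200-term evaluation to far better than 1%.

Electrode positions come from an idealized spherical extended 10-20
construction (midline arc in 18-degree steps, outer ring at 72 degrees,
arc interpolation in between).  These are synthetic, geometric positions,
not digitized cap coordinates; they put Cz at the vertex and give the
fronto-central montage its expected neighborhood structure, which is all
the downstream analyses rely on.

Each source's gain block is rescaled so that its largest attainable
absolute channel gain is 1.  Source amplitudes stated in microvolts are
therefore directly interpretable as best-channel scalp amplitudes — a
deliberate convention, since a spherical stand-in cannot reproduce the
absolute gain structure of an anatomical head model (see *Calibration*).

An externally computed lead field (for example an export of an anatomical
head model) can be supplied through `load_leadfield()`, which validates
shapes, finiteness, and orientation norms.

# The generative ERP model

Each experimental condition is a mixture of Gaussian peaks:

* **Error condition**: P200, N250, P320, N450 — peaks at 200/250/320/450
  ms with source amplitudes +20/−40/+50/−40 µV and widths 50/50/120/150 ms,
  generated on every trial.
* **Correct condition**: positive peaks at 270 ms (20 µV, width 200 ms)
  and 350 ms (10 µV, 250 ms) whose per-subject generation probabilities are
  drawn uniformly in [0.5, 1], plus an always-present negativity at 450 ms
  (−40 µV, 150 ms).

A peak of width $w$ is rendered as a Gaussian with $\sigma = w/6$, so the
stated width spans ±3σ.  Trial-to-trial variability follows the
convention of simulation toolboxes in this field: every parameter
(latency, width, amplitude) receives a zero-mean truncated-normal
perturbation with the stated deviation (20% of the value) as its *maximum*
and $\sigma = \text{max}/3$; one epoch-wide latency shift bounded at
±100 ms moves the entire complex.  The shift uses the same
truncated-normal convention as all other deviations.  We considered a
uniform shift on [−100, 100] ms, but a uniform shift smears the class
averages so strongly that the early positivity of the error-minus-correct
difference wave (observed near 184 ms) disappears; the truncated-normal
convention, which is also what the established ERP simulation toolboxes
implement, reproduces the expected grand-average morphology and is the
package default.

Subject-to-subject variability has three sources: component dipole
locations are re-drawn per subject uniformly among lead-field sources
within 10 mm of the component center; orientations are the Cz-gain-optimal
direction perturbed component-wise by ±20% and renormalized; and the
correct-condition peak probabilities are per-subject draws.  Component
source centers are configurable; the defaults place all components in the
medial fronto-central cortex (midline, 52–62 mm superior), chosen so the
projections peak at FCz/Cz as expected for interaction ErrPs.  They are
deliberately generic, synthetic coordinates, not a literature
localization.

# Background noise and calibration

Background activity is brown noise (cumulative sum of white Gaussian
increments, linearly detrended; power spectral density $\propto 1/f^2$)
projected from 80 sources at least 25 mm apart, each rescaled per epoch to
a maximum absolute amplitude of 37.5 ± 0.5 µV ("±" read as a uniform
bound).  Source orientations are random unit vectors fixed per subject.
The 80-at-25 mm constraint sits close to the packing limit of a discrete
source cloud inside a 75 mm ball, so `pick_spaced_sources()` uses
randomized best-candidate placement (each step keeps the candidate
farthest from the already-chosen set among a random batch) rather than
naive rejection, which stalls a few sources short.

**Calibration.**  A spherical three-shell stand-in cannot match the
absolute signal-to-noise ratio that a specific anatomical lead field
produces, and classification difficulty — not absolute microvolts — is
what every downstream result depends on.  The package therefore fixes a
single scalar `noise_gain` multiplying the summed projected noise, and
documents the calibration procedure in `calibrate_noise_gain()`: scan a
gain grid, simulate a few subjects per candidate at the full default
configuration, run the subject-specific repeated-CV pipeline, and select
the gain whose mean balanced accuracy is closest to 0.82 (the canonical
within-subject operating point for this paradigm).  Several calibration
subjects are averaged because the subject-level spread of balanced
accuracy at a fixed gain is about ±5 percentage points — larger than the
calibration resolution, so a single-subject calibration would mostly
measure which subject was drawn.  Running this procedure selected
`noise_gain = 0.25`, which ships as the default.  The calibration targets
only the within-subject operating point; transfer gaps (generic and LOSO
performance) are emergent, not calibrated.

# Decoding pipeline

**Features.**  Mean amplitude in eight overlapping half-open windows
[0,100), [100,200), [150,250), [200,300), [250,350), [300,400), [350,450),
[400,500) ms at the eight fronto-central channels FC1, FC2, C3, Cz, C4,
CP1, CP2, Pz — 64 features per trial, ordered channels-outer.  Half-open
intervals keep the overlapping slots well-defined at shared endpoints.
Features are z-scored with statistics estimated on training data only and
applied frozen to evaluation data; "normalize over all trials" would leak
test statistics into training, so the package deliberately scopes the
normalizer to the training portion of every split.

**Classifier.**  RBF-kernel SVM with class weights inversely proportional
to the pre-downsampling class frequencies, and majority-class random
downsampling applied to training data only (both mechanisms are applied,
as each covers a different part of the pipeline: weights shape the loss,
downsampling balances the sample).  Hyperparameters are searched
exhaustively over cost $10^{-6}\ldots10^6$ and gamma $10^{-5}\ldots10^5$
(143 pairs; a 7×6 reduced grid is provided for desk-scale runs).  A
sampler-based optimizer over a finite 143-point grid cannot beat
exhaustive enumeration, so enumeration is used.  Model selection uses
stratified inner cross-validation (default 5 folds; 3 at desk scale) with
downsampling and normalizer fitting inside each inner training fold and
balanced accuracy on the untouched imbalanced inner fold as the
criterion; ties prefer the smallest cost, then the smallest gamma
(smoother models).  Stratification guarantees error trials in every fold
at 20% prevalence.

**Regimes.**
*Subject-specific*: repeated stratified 10-fold CV (10 repeats at full
scale), grid search inside every outer training portion, metrics on
untouched imbalanced folds.
*LOSO*: pool all other subjects, downsample (optionally capped,
class-balanced), fit normalizer and grid-searched model, test on the full
held-out subject.
*Generic*: pool the simulated training subjects, fit once, freeze; no
adaptation of any kind at application time.

A leakage audit is part of the test suite: per-fold provenance records
which trials fitted the final model and normalizer, and the tests assert
those index sets are disjoint from the test fold and reproduce the stored
normalizer statistics exactly.

# Statistical evaluation

* **Balanced accuracy** (error = positive class): mean of TPR and TNR;
  robust at 20% prevalence.
* **Cross-validated permutation test**: the full pipeline statistic is
  recomputed under label permutations; $p = (\#\{b^* \ge b\} + 1)/(M+1)$.
  When the evaluated model is a frozen generic classifier its predictions
  do not depend on the labels, so permuting labels and re-scoring is the
  exact permutation distribution at negligible cost; re-searching
  hyperparameters inside every permutation is supported in principle by
  passing a pipeline closure that does so, but is disproportionate (143
  fits × permutations) and not the default.
* **Paired Wilcoxon signed-rank** comparisons between regimes: zeros
  dropped, midranks for ties, exact null distribution (sign-assignment
  enumeration via a rank-sum convolution over doubled ranks) for up to 25
  retained pairs, normal approximation with tie and continuity corrections
  beyond.  The exact path is verified against brute-force enumeration of
  all $2^n$ sign assignments in the tests.
* **Pointwise class differences**: Welch two-sample t-test per timepoint
  with Benjamini-Hochberg FDR across timepoints.  The pointwise statistic
  is a package choice (a t-statistic is the standard default for
  two-condition ERP amplitude comparisons).
* **Diagnostics**: averaged single-trial FFT amplitude spectra; the
  permuted baseline-RMS noise distribution (per-trial per-channel RMS over
  the 200 ms pre-onset window, averaged over electrodes, then trials, then
  subjects); ERP images (error trials minus the correct average, moving
  average over five consecutive trials, window truncated at the trial
  sequence edges — edge handling is a package choice).
* **Peak picking**: the most prominent peak of a difference wave in an
  interval is the sample of maximal signed amplitude (maximum for positive
  polarity, minimum for negative); a monotone segment therefore reports an
  interval endpoint.

# Default study conditions and problem sizes

The default configuration simulates 250 Hz epochs of 1.5 s (0.5 s
pre-stimulus; 375 samples), 1200 epochs per subject with exactly 20%
error trials in shuffled positions (a fixed count, not a Bernoulli draw,
which matches a fixed-rate protocol and stabilizes estimates), 15
training and 10 validation subjects, on the 64-channel BioSemi montage.
One master seed derives all per-subject seeds, and each subject consumes
its random draws in a documented order, so every dataset is reproducible
from a single integer.

The package's own reproduction runs (`scripts/acceptance.R`, and the
corresponding test blocks) use desk-scale problem sizes chosen as a
deliberate compromise between Monte-Carlo stability and a desktop-class
compute budget: grand-average analyses use the full 15 × 1200-epoch
training set, while the classification regimes use 600 epochs per
subject, 8 training subjects, the reduced 7×6 hyperparameter grid, 3
inner folds, class-balanced caps of 1600 (generic) / 600 (LOSO) pooled
training trials, 2 CV repeats on 3 subjects for the subject-specific
regime, and 200 permutations for the significance test.

# What the simulation does and does not emulate

The generator reproduces the statistical structure that matters for
single-trial ErrP decoding: class-specific multi-peak morphology,
latency/width/amplitude jitter, whole-complex latency shifts, per-subject
source geometry and orientation variability, probabilistic peak
generation in the correct condition, and spatially dispersed 1/f²
background activity.  It does not emulate ocular or muscular artifacts,
electrode drift/pops or impedance differences, habituation or fatigue
trends, inter-trial overlap of slow components, or anatomical
(non-spherical) conduction.  Passing results therefore demonstrate that
the pipeline recovers the intended effects under the modeled variability
— they do not certify performance on any particular recorded dataset,
where those unmodeled factors reduce transfer accuracy further.

# Known limitations

* The spherical montage and head are idealized; topographies are
  qualitatively, not anatomically, fronto-central.
* Component source centers are synthetic defaults, configurable but not
  fitted to localization literature.
* Continuous-recording support covers the preprocessing chain on
  in-memory containers; vendor file formats are out of scope here.
* The permutation test defaults to frozen hyperparameters inside
  permutations (see above); the fully re-searched variant is available
  but computationally disproportionate.
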