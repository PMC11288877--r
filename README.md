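# errpsim

Simulation and single-trial classification of error-related potentials
(ErrPs) in EEG.

## The problem

ErrPs are stereotyped EEG deflections elicited when a person perceives an
error — including errors made by a machine interface they are using.
Brain-computer interfaces (BCIs) can exploit single-trial ErrP detection
for error correction, but training a subject-specific ErrP decoder
requires a tedious calibration session for every new user.  A promising
alternative is a *generic* decoder trained on simulated subjects: if the
simulation captures the trial-to-trial and subject-to-subject variability
of the real signal, a classifier trained purely in silico should transfer
to unseen subjects.

`errpsim` implements the full experimental machinery to study that
question, for researchers in BCI / neural signal processing:

* an analytic **three-shell spherical forward model** (brain/skull/scalp,
  radii 80/85/92 mm, conductivities 1 : 1/80 : 1, Legendre series solved
  per harmonic order) with an idealized extended 10-20 montage, plus a
  reader for externally computed lead fields;
* a **generative ERP model**: the error condition as a P200–N250–P320–N450
  Gaussian-peak complex (+20/−40/+50/−40 µV at source, widths
  50/50/120/150 ms), the correct condition as a P270/P350 complex with an
  N450, all parameters jittered per trial by truncated-normal deviations
  bounded at 20%, a ±100 ms whole-complex latency shift, per-subject
  source jitter (10 mm), orientation deviation (±20%) and probabilistic
  correct-condition peaks;
* **brown-noise background** from 80 sources ≥ 25 mm apart at
  37.5 ± 0.5 µV, with a documented signal-to-noise calibration;
* the **decoding pipeline**: mean amplitudes in eight overlapping
  [0–500] ms windows at eight fronto-central channels, z-scored on
  training data only, classified by a class-weighted RBF SVM with
  exhaustive cost/gamma grid search, majority-class downsampling in
  training folds, and stratified repeated cross-validation;
* three **evaluation regimes** — subject-specific, leave-one-subject-out
  (LOSO), and generic (train on pooled simulated subjects, freeze, apply
  without adaptation) — with balanced accuracy (error = positive class),
  cross-validated permutation tests, exact paired Wilcoxon signed-rank
  comparisons, FDR-corrected pointwise ERP statistics, grand averages and
  peak picking, ERP images, single-trial spectra and baseline-RMS noise
  diagnostics;
* a **preprocessing chain** for recorded EEG (downsampling, zero-phase
  Hamming-sinc FIR band-pass and notch, bad-channel detection and
  interpolation, common-average reference, epoching with baseline
  correction).

The statistic at the core is the balanced accuracy
`bACC = (TPR + TNR) / 2`, with the error class positive, evaluated under
the three regimes above; significance is assessed by permutation
(`p = (#{b* ≥ b} + 1)/(M + 1)`).

## Worked example

```r
library(errpsim)

lf  <- build_spherical_leadfield(seed = 1)        # 64 ch x 8000 sources
cfg <- sim_config(n_epochs = 600, n_train_subjects = 3, n_val_subjects = 2,
                  master_seed = 7)
ds  <- simulate_dataset(cfg, lf)

ds$training[[1]]
#> <epochs_data> subject 'train01': 600 trials (120 error) x 64 channels x 375 samples @ 250 Hz

# grand-average ERP analysis at Cz
ga <- grand_average(ds$training, "Cz")
find_peaks(ga$times_ms, ga$difference,
           data.frame(start_ms = c(50, 250), end_ms = c(250, 400),
                      polarity = "positive"))
#>   start_ms end_ms polarity latency_ms amplitude
#> 1       50    250 positive        172  1.266111
#> 2      250    400 positive        340 12.005357

# generic decoder: train on the simulated training subjects, freeze,
# apply to an unseen validation subject
ec  <- eval_config(grid = reduced_svm_grid(), inner_folds = 3)
set.seed(1)
gen <- train_generic(ds$training, ec)
unlist(apply_model(gen, ds$validation[[1]], ec)[c("tpr", "tnr", "bacc")])
#>       tpr       tnr      bacc
#> 0.7916667 0.8479167 0.8197917
```

The difference wave (error − correct) shows the expected ErrP morphology:
a small early positivity, the dominant positive deflection near 320 ms,
and the classifier trained only on simulated subjects decodes an unseen
simulated subject well above the 0.5 chance level of a balanced metric.

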