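Package: errpsim
Title: Simulation and Single-Trial Classification of Error-Related Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-model simulation of error-related potential (ErrP) EEG
    epochs and the single-trial classification pipeline used to study generic,
    leave-one-subject-out and subject-specific decoders. Provides an analytic
    three-shell spherical head model, a parameterized event-related-potential
    generator with trial- and subject-level variability, brown-noise background
    activity, windowed-mean feature extraction, class-weighted RBF support
    vector machines with exhaustive hyperparameter search, and an evaluation
    suite (balanced accuracy, cross-validated permutation tests, exact Wilcoxon
    signed-rank comparisons, FDR-corrected pointwise ERP statistics, ERP images
    and signal-quality diagnostics).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
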