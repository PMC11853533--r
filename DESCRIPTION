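Package: hybridbci
Title: Hybrid Dry-EEG and Pupillary-Light-Reflex Brain-Computer Interface Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decoding toolkit for a four-target hybrid brain-computer interface
    that combines dry-electrode EEG and binocular pupillometry. Implements LED
    stimulus schedule generation (steady-state and pattern modes), a synthetic
    physiological-signal generator (flash visual evoked potentials, steady-state
    visual evoked potentials, pupillary light reflex, chewing EMG), shared signal
    processing (referencing, zero-phase IIR band-pass, global field power,
    covariance estimation, epoching), a multivariate-synchronization-index SSVEP
    detector, Morse-wavelet spectro-temporal pupil features with a 1-D temporal
    convolutional network classifier trained with center loss, transition-locked
    FVEP peak-to-valley features with per-LED support vector machines, Riemannian
    (affine-invariant) covariance-distance task-onset detection with a pupil
    fallback, fusion of the evidence streams, evaluation harnesses (accuracy,
    Wolpaw information transfer rate, cross-validation, PERMANOVA, Wilcoxon), and
    a deterministic meal-assist-robot trigger state machine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    vegan,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
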