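Package: somnet
Title: Sleep Stage Classification from Single-Channel EEG Spectrograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for automatic sleep staging from a single
    EEG channel. Thirty-second polysomnography epochs are converted to
    cropped, colormapped time-frequency images by a deterministic
    resample/STFT/rasterize pipeline, and classified into the five AASM
    stages (W, N1, N2, N3, REM) by a compact residual convolutional network
    coupled to a two-layer bidirectional LSTM that learns stage-transition
    structure across ten-epoch sequences, trained with an auxiliary
    classifier loss. Includes EDF/EDF+ reading and writing, R&K to AASM
    label mapping, subject-wise and epoch-wise k-fold cross-validation, a
    full evaluation suite (confusion matrices, per-class precision, recall
    and F1, accuracy, macro-F1, Cohen's kappa, hypnogram transition counts),
    and a synthetic sleep-EEG generator with stage-conditioned spectral
    recipes and Markov hypnograms for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    caret,
    optparse,
    yaml,
    jsonlite,
    withr
Config/testthat/edition: 3
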