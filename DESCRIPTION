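Package: fingermeg
Title: Source-Space Decoding of Finger Movements from MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for decoding individual finger movements from
    magnetoencephalography (MEG): EMG-based movement onset detection and
    reaction/movement timing, band-limited epoch preprocessing, linearly
    constrained minimum variance (LCMV) beamforming with max-variance
    orientation selection, movement-related activation-index mapping in
    full-epoch and 50-ms windows, Morlet time-frequency analysis with an
    evoked/induced decomposition, cross-validated one-versus-rest linear
    classification over several spatial feature-extraction schemes,
    virtual-channel window combination, voting-based digit maps, and the
    accompanying nonparametric statistics (Friedman, Wilcoxon signed-rank,
    Benjamini-Hochberg, cluster-based permutation). A forward-model
    simulator generates sensor epochs and EMG traces with full ground
    truth so every stage is testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
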