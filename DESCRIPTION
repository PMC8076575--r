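Package: crydetect
Title: Infant Cry Detection and Cry-Sequence Biomarkers from Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting infant crying in audio
    recordings and deriving cry-sequence digital biomarkers. Audio is
    segmented into non-overlapping 5-second epochs, summarised by
    frame-level acoustic descriptors (mel-frequency cepstral coefficients,
    mel-band energies, voicing probability, pitch, energy, zero-crossing
    rate) reduced with statistical functionals, screened for robustness
    across re-recording conditions, and classified with cross-validated
    models selected by Matthews correlation coefficient with
    sensitivity-prioritised hyperparameter choice. Per-epoch cry labels are
    post-processed into cry sequences via start/stop hysteresis criteria,
    and cumulative cry-count curves quantify robustness across perturbed
    conditions. A synthetic generator produces cry and non-cry audio,
    labelled sessions, and perturbed re-recordings so every stage is
    testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    ranger,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
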