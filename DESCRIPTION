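Package: tsktransfer
Title: Online Selective Transfer TSK Fuzzy Classification with Joint
    Distribution Adaptation and Manifold Regularization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains first-order Takagi-Sugeno-Kang (TSK) fuzzy classifiers
    that transfer knowledge from multiple labeled source domains to a target
    domain observed only through a handful of online calibration epochs, as
    arises in EEG-based seizure detection across recording sessions or
    subjects. The transfer objective combines a weighted squared loss over
    source and calibration objects, maximum-mean-discrepancy adaptation of
    both the marginal and class-conditional output distributions, and a
    normalized-graph-Laplacian manifold penalty, and is solved in closed
    form. Candidate source domains are ranked by class-mean distance and
    selected by exact one-dimensional 2-means; per-source models are
    combined into a training-accuracy-weighted ensemble. Also provides
    wavelet, short-time-Fourier and kernel-PCA band-energy feature
    extractors for raw single-channel EEG segments, a synthetic generator
    of shifted multi-domain data for end-to-end testing, and an online
    calibration evaluation harness with the standard source-only,
    target-only and pooled baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    kernlab,
    signal,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
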