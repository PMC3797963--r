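Package: catmeg
Title: Time-Resolved Category Discriminability and Decoding for MEG Epochs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for feedback-driven visual category learning
    experiments recorded with magnetoencephalography (MEG). Generates
    two-category "blob" polygon stimulus spaces with parametric Gaussian
    jitter, simulates sensor- and source-space epoch tensors with
    learning-modulated, latency-windowed category effects, and implements the
    time-resolved multivariate analysis: sliding-window Hotelling T-squared
    (chi-squared) discriminability traces after 99%-variance PCA reduction,
    excursion (cluster) permutation tests with Fisher combination across
    subjects, and window-averaged leave-one-trial-out logistic decoding of
    category compared across early and late learning phases and pooled by
    cortical pathway.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
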