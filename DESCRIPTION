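Package: dftune
Title: Discriminative Fine-Tuning Schedules for Small-Data Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A training toolkit for transfer-learning classifiers on small
    grayscale image datasets. Implements discriminative fine-tuning: per-layer
    triangular learning-rate and momentum schedules driven by a learning-rate
    range test, a momentum-velocity parameter update, an emulated
    mixed-precision step with loss scaling, a medical-image augmentation
    pipeline (Gaussian blur, gamma intensity shift, small rotation, white
    noise) with random minority oversampling, multiclass confusion-matrix
    metrics (per-class sensitivity and specificity), a compact built-in
    convolutional network, and a seeded synthetic image generator so the whole
    pipeline is testable end to end on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
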