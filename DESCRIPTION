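Package: breathtex
Title: Breathing-State Identification from Respiratory Sound Spectrogram Texture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects sputum accumulation in intubated patients from
    respiratory audio. Recordings are segmented into single breaths with a
    short-time autocorrelation two-threshold rule, each breath is rendered
    as a decibel-scaled power spectrogram image, vertical (sputum-related)
    texture is enhanced with an edge mask, Laplacian-of-Gaussian filtering
    and a triple-threshold line extender, grey-level co-occurrence matrix
    texture features are extracted at four angles, ranked by information
    gain, and classified with a ridge-penalised logistic model under
    stratified 10-fold cross-validation. Includes a seeded synthetic
    respiratory-audio generator so the full pipeline is testable without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
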