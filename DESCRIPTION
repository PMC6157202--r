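Package: msldSampEn
Title: Multidistance Signal Level Difference Sample Entropy for EEG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification of single-channel EEG
    recordings via sample entropy computed on the Multidistance Signal
    Level Difference (MSLD) transform. The MSLD transform takes absolute
    differences of a signal at sample distances d = 1..K; sample entropy
    of each difference signal yields a per-distance complexity profile
    that separates ictal (seizure), interictal and normal EEG. Includes
    readers for one-sample-per-line ASCII records, a seeded three-class
    synthetic signal generator, support vector machine classification
    with linear and polynomial kernels under stratified k-fold
    cross-validation, an accuracy-grid driver over tolerance and scale
    ranges, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
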