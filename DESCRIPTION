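Package: subrand
Title: Entropy-Based Measures of Subjective Randomness for Binary Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores binary sequences with measures of perceived (subjective)
    randomness: second-order (digram) entropy under the Shannon, Renyi and
    Marcellin (asymmetric) families, and the Difficulty Predictor obtained by
    minimal-cost segmentation into runs and alternating blocks. Includes a
    constrained Differential Evolution optimizer that fits Renyi's order alpha
    or Marcellin's four digram weights to mean randomness-rating curves,
    generators for the classical 21-symbol rating stimuli and the 128 canonical
    octograms, synthetic rating curves for parameter-recovery studies, and a
    correlation-based validation stage against observed rating tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
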