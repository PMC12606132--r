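Package: pinboost
Title: Predicted-Spectrum Rescoring Features for Percolator Input Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Adds machine-learning rescoring features to Percolator input
    (.pin) tables from peptide-property predictions. Parses a practical
    subset of ProForma 2.0 peptidoform notation, reads and writes pin and
    Mascot Generic Format (MGF) files, computes the unweighted spectral
    entropy similarity and delta-RT-loess features, calibrates the
    normalized collision energy (NCE) of intensity predictors against the
    experimental spectra, and runs a heuristic best-model search across
    candidate predictors. A deterministic synthetic prediction backend
    with known ground truth makes every step testable without network
    access or trained model weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
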