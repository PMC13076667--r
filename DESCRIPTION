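Package: caensembles
Title: Calcium-Imaging Ensemble and Fiber-Photometry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vivo calcium recordings of neuronal
    ensembles. Computes isosbestic-corrected dF/F from two-channel fiber
    photometry, detects significant calcium transients with MAD thresholds,
    and quantifies peri-event AUC and peak responses. For single-neuron
    miniscope traces it performs peri-event baseline z-scoring, classifies
    stimulus-responsive neurons, matches cells across sessions by centroid
    proximity, and tests ensemble overlap against a marginal-preserving
    permutation null with an exact hypergeometric oracle. Also normalizes
    monosynaptic rabies-tracing input counts into per-region input indices.
    Ships a synthetic-data generator with known ground truth for end-to-end
    validation.
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
    pracma,
    purrr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
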