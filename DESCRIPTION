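Package: popdecode
Title: Optimal Linear Decoding of Neural Population Spike Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how well linear readouts discriminate
    sensory stimuli from population spike counts. Implements the Fisher
    linear discriminant solution that maximizes the average signal-to-noise
    ratio across a stimulus set (groupwise-optimal decoding), its per-pair
    closed form (pairwise-optimal decoding), pooling and best-neuron
    references, criterion-sweep ROC discriminability, eigenvalue-based
    signal and noise correlation indices with population-size bias
    correction, trial- and stimulus-shuffling controls, weight-perturbation
    geometry in a Gram-Schmidt orthogonalized eigenbasis, split-half
    generalization, and cross-adaptation analyses. A seeded synthetic
    spike-count generator with sigmoidal amplitude tuning, copula-based
    noise correlation, and adaptation modeled as tuning-curve shift plus
    alignment makes every analysis testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
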