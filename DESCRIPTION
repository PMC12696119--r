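Package: perceptscale
Title: Perceptually Ordered Stimulus Continua: Design, Scaling and Memory Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for constructing and validating perceptually ordered
    naturalistic stimulus continua. Provides spherical interpolation between
    generative-model noise latents, distance-based anchor/guide and continuum
    selection with pluggable perceptual-distance backends, triplet
    (method-of-triads) session design, synthetic noisy observers, perceptual
    scaling by maximum likelihood difference scaling (MLDS), soft ordinal
    embedding (SOE) and t-distributed stochastic triplet embedding (t-STE)
    with cross-validated triplet error, and a delayed match-to-sample memory
    task generator with a Bayesian hierarchical logistic accuracy model
    fitted by MCMC.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
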