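Package: stdtsim
Title: Simulation and Mass-Univariate Analysis of Somatosensory Temporal
    Discrimination EEG Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse EEG studies of somatosensory
    temporal discrimination. Provides psychophysical observer models with
    logistic psychometric functions, adaptive staircase calibration
    (detection threshold and temporal discrimination threshold),
    maximum-likelihood psychometric fitting, an individually calibrated
    10-level interstimulus-interval design, a visuo-tactile matching-task
    trial engine that dissociates percept from report, Bayes-factor
    statistics for behaviour (JZS paired test and a Dirichlet-multinomial
    test of association), a 64-channel synthetic EEG generator with
    somatosensory evoked components and a percept-dependent fronto-central
    modulation, a preprocessing chain (filtering, re-referencing, blink
    removal, epoching, artifact rejection, baseline correction, scalp-grid
    interpolation), and mass-univariate spatiotemporal inference with
    cluster-level family-wise error control by sign-flip permutation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    interp,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
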