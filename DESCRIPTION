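Package: contrastLN
Title: Contrast Gain Control in Linear-Nonlinear Auditory Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying auditory contrast gain control with
    linear-nonlinear (LN) encoding models. Generates dynamic random chord
    (DRC) stimuli in defined contrast regimes (including switching-contrast
    and level-matched variants), simulates ground-truth LN neurons with
    contrast-dependent sigmoid output nonlinearities, Poisson spiking and
    known adaptation time constants, screens units by response reliability
    (signal/noise power and cross-validated prediction), fits separable
    spectro-temporal receptive fields and per-condition output
    nonlinearities, quantifies gain compensation and y-offset adaptation,
    fits a time-constant-augmented contrast-dependent LN model to
    switching-contrast data, and predicts 2-AFC level-discrimination
    behavior (psychometric curves, just-noticeable differences, perceptual
    compensation) from populations of model neurons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
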