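Package: fbgtwin
Title: Heat- and Mass-Balance Digital Twin for Batch Fluid-Bed Granulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulates the granule moisture (loss-on-drying, LOD) and
    temperature trajectories of batch fluid-bed granulation processes with a
    two-compartment heat- and mass-balance ordinary differential equation
    model, and wraps the model in the industrial workflow needed to use it as
    a digital twin: parameter calibration from batch LOD records with RMSE
    acceptance gates and train/validate/verify cross-validation, scenario
    based input-variability ("risk fingerprint") analysis over wet and dry
    disturbance scenarios at several inlet-air humidity levels, and
    quasi-Monte-Carlo propagation of parameter uncertainty into pointwise
    LOD uncertainty bands combined with input extremes into an overall
    output-uncertainty envelope.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    pracma,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
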