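Package: eidecomp
Title: Decomposition and Summation Analysis of Stimulus-Evoked Synaptic
    Conductances
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for dual-pathway synaptic integration
    experiments in voltage and current clamp. Reconstructs time-varying
    excitatory and inhibitory synaptic conductances from voltage-clamp
    sweep sets by per-timepoint linear I/V regression, quantifies how two
    converging inputs summate via an exponentially weighted non-negative
    scale-factor fit, detects stimulus-evoked responses and action
    potentials, processes photodiode-array voltage-sensitive dye
    recordings, and provides the accompanying statistical procedures
    (one-sample Z test, Student's t tests, Pearson skewness, pointwise
    trace comparison). A seeded synthetic-data generator produces
    conductance kernels, ideal voltage-clamp sweeps, leaky
    integrate-and-fire current-clamp traces and diode-array recordings
    with the statistical structure the analysis assumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
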