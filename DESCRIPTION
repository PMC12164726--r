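Package: TransientGate
Title: Transient-Gated Decoding of Intracortical Population Activity
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies effector-specific onset and offset transient
    components in motor-cortex population spiking and uses them to gate
    short-window feature decoders (finger identity, grasp force) whose
    outputs are latched until an offset transient is detected. Provides
    the full analysis chain: a seeded Poisson population-spiking
    simulator with planted latent structure, causal firing-rate
    preprocessing, a 20-factor latent model with orthonormal basis,
    transient component identification via subspace decomposition and
    varimax rotation, condition-dependent variance analyses, the gated
    streaming state-machine decoder, Wiener-cascade and discriminant
    baselines, and a leave-one-out evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
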