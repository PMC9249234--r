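Package: spikerank
Title: Rank-Controlled Feedback Learning in Recurrent Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and supervised training of discrete-time recurrent
    networks of leaky integrate-and-fire neurons under a family of
    surrogate-gradient learning rules in which the rank R of the error
    feedback matrix and the spike-timing tolerance tau-star are explicit
    parameters.  Low feedback rank recovers error-broadcast rules of the
    e-prop type, full rank recovers target-based rules (full-FORCE, learning
    through target spikes), and tau-star interpolates between precise
    spike-timing codes and rate codes.  Includes a store-and-recall benchmark
    task, a button-and-food navigation task with a built-in expert for
    behavioral cloning, and estimators of the dimensionality of the space of
    internal solutions (multi-replica principal-component analysis and a
    single-trial synaptic-noise probe) via the participation ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
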