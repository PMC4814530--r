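Package: dendnet
Title: Multiclass Classification with Nonlinear Dendrites and Structural Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multiclass spike-pattern classifier built from neurons with
    nonlinear dendrites and binary (connection-multiplicity) synapses.
    Learning is structural: a correlation-based rule rewires a sparse integer
    connection matrix rather than adjusting analog weights. The package
    provides the rate-based reduced model with winner-take-all readout and
    per-class margins, the structural-plasticity training loop with
    local-minimum escapes and margin calibration, class-specific adaptive
    dendrite growth with cross-validation stopping, an ensemble combiner over
    independently seeded classifiers, combinatorial storage-capacity theory
    with optimal-topology search, a leaky integrate-and-fire spiking
    evaluation path with single-spike and Poisson encoders, a two-tier
    address-event (AER) sparse-connectivity memory model with bit and area
    accounting, and synthetic data generators (binary prototype patterns,
    DVS-style event streams, IDX image reading).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
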