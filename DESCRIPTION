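Package: ipcmodel
Title: Information Processing Capacity Modelling of Regional BOLD Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models event-related neuronal activity of a brain region as a
    first-order linear system driven by the information arrival rate, with
    processing capacity p (bit/s) and input storage capacity m (bits) as
    parameters. Provides the forward chain (impulse-driven activity,
    two-state excitatory/inhibitory responses, double-gamma hemodynamic
    convolution, TR sampling, additive noise), a flanker-style event-related
    design simulator with known ground truth, and the full inversion:
    least-squares hemodynamic deconvolution of trial-averaged BOLD impulse
    responses, cubic-spline upsampling, fitting of the two-state
    excitatory/inhibitory response, selection of fixed or flexible
    hemodynamic response functions by mean squared prediction error, and
    derivation of relative capacities (p/alpha, m/alpha) and circuit time
    constants T_c = m/p, validated by parameter recovery on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
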