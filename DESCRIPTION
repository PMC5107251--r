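Package: condlearn
Title: Unified Simulation of Classical and Operant Conditioning via
    Neuromodulated Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates associative learning with a single neuromodulated
    plasticity rule. A layered winner-take-all action network carries
    log-odds synaptic weights w = ln(nr/nbar) built from reward and
    no-reward counts, and a simulated dopaminergic signal (a sigmoid of
    the change in a scalar "ideal degree" of the perceived state) decides
    which count is incremented. The package reproduces, entirely in
    simulation, Pavlovian acquisition and extinction of a conditioned
    response and Thorndike-style puzzle-box operant learning with network
    growth, entropy-based convergence, long-term memory persistence
    across runs, and a Rescorla-Wagner baseline for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
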