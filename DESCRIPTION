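Package: MarkovBlankets
Title: Markov Blanket Analysis of Multiscale Neural Dynamical Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing directed dependency graphs of neural
    dynamical models (conductance-based neurons, neural-mass units, canonical
    cortical microcircuits), extracting and classifying Markov blanket
    partitions into internal, sensory, active and external states, verifying
    the implied conditional independencies both structurally (d-separation on
    one-step unrolled graphs) and statistically (nested-regression tests on
    simulated trajectories), and coarse-graining blankets recursively across
    spatial scales, from single neurons to cortical columns to networks of
    columns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'MarkovBlankets-package.R'
    'accessors.R'
    'depgraph.R'
    'neuromodels.R'
    'simulate.R'
    'fixtures.R'
    'multiscale.R'
    'verify.R'
    'io.R'
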