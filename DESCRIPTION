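Package: oligocleave
Title: Replicator Dynamics of Cleavage-Driven Templated Oligomer Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Population-dynamics models of templated (non-enzymatic)
    replication of information-coding oligomers in a chemostat, where chain
    cleavage generates the primers that drive proliferation. Implements the
    random-cleavage model (analytic steady states) and a catalyzed-cleavage
    model with four cooperating subpopulations (substrates, catalysts and
    their complements), together with the dynamical-systems toolkit built on
    them: fixed-point location and stability on the symmetric subspace,
    natural-parameter continuation in the catalytic rate, existence windows
    and their disappearance threshold, basin-of-attraction classification,
    minimal seeding ratios, ecosystem fitness, fitness landscapes and a
    Metropolis Monte Carlo co-evolution of the catalytic parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
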