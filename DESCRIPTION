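Package: cellreorient
Title: Mechanochemical Simulation of Cell Reorientation Under Cyclic Stretch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the coupled dynamics of focal-adhesion bond clusters
    and contractile stress fibers in spindle-shaped cells adhering to
    cyclically stretched elastomeric substrates. Bond dissociation follows
    Bell-type kinetics driven by a force-dependent binding-energy reduction;
    each stress-fiber filament is a constant contractile force in parallel
    with a Maxwell (spring-dashpot) element; the substrate may strain-stiffen
    with a 3/2 power law above a critical strain. Provides closed-form steady
    states and their linear stability on static substrates, single-cell
    trajectories and collapse detection under stretch protocols, long-time
    average stress-fiber density across orientations, and a population-level
    reorientation Monte Carlo (attach, assess, detach, rotational-diffusion
    hop) tracked by the nematic order parameter, with exponential decay-time
    fitting. Includes a command-line interface and CSV/JSON outputs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
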