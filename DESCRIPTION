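Package: sarclat
Title: Spatially Explicit Half-Sarcomere Lattice Simulation of Crossbridge
    Cycling and Work Loops
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte Carlo simulation of a spatially explicit half-sarcomere:
    compliant thick and thin filament chains on a periodic hexagonal lattice,
    two-spring (linear plus torsional) myosin heads cycling through a
    three-state kinetic scheme with strain-dependent rates, an exponential
    titin element, and prescribed myofilament lattice (d10) spacing
    trajectories. Drivers simulate isometric twitch and tetanus, cyclic work
    loops at in vivo strain amplitudes and frequencies, and parameter sweeps
    over activation phase, lattice spacing, crossbridge stiffness, and titin
    stiffness, reporting mass-specific net work per cycle.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
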