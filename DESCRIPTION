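Package: cellhop
Title: Phase-Field Simulation and Data-Driven Inference of Confined Cell Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a single crawling cell on adhesive micropatterns with a
    two-dimensional phase-field model. The cell shape is a smooth indicator
    field evolved under Cahn-Hilliard line tension, an area constraint and an
    active motility force driven by a stochastic polarity field; the cell
    senses micropattern geometry through polarity inhibition off the pattern
    and a filopodial placement rule for new protrusive activity. The package
    also implements the companion data-driven pipeline that reconstructs the
    deterministic equation of motion F(x,v), the conditional mean acceleration
    of the cell centre of mass, from trajectory ensembles, traces its phase
    portrait, classifies the dynamics as limit cycle, bistable or stationary,
    and quantifies sampling variability by bootstrap. Synthetic stochastic
    differential equation generators (Ornstein-Uhlenbeck, van der Pol, damped
    double well) with known drift validate the inference stage independently
    of the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
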