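Package: plateletsim
Title: Multi-Scale Simulation of Deformable Platelet Adhesion in Shear Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-dimensional multi-scale simulator of deformable platelets
    tethering to a vessel wall under shear flow. Couples a hybrid membrane model
    (spring-network cytoskeleton with area/volume constraints and Helfrich-type
    bending of the lipid bilayer), a stochastic GPIb-alpha/von Willebrand factor
    adhesive-dynamics model with Bell dissociation and Dembo association kinetics,
    a D3Q19 lattice Boltzmann fluid with Guo forcing and on-site velocity walls,
    and immersed-boundary fluid-structure coupling. Includes validation
    experiments (Jeffery orbit of an oblate spheroid, tether pause-time
    statistics and off-rate estimation) and reduced-scale predictive experiments
    on membrane stiffness, receptor count and platelet-platelet interaction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
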