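Package: nanopost
Title: Coarse-Grained Dynamics of Polymers Confined in Nanopost Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained molecular dynamics and analysis of flexible and
    semiflexible bead-spring polymers, of linear or circular topology,
    confined in a square-lattice array of parallel nanoposts. The model
    combines FENE bonds, purely repulsive Weeks-Chandler-Andersen excluded
    volume, a discretized worm-like-chain bending potential, and repulsive
    bead-post interactions; trajectories are generated with a leap-frog
    integrator under Nose-Hoover or Langevin thermostats. Analysis tools
    compute the chain span along the post axes, gyration tensor components,
    interstitial occupation number, single-chain structure factor, tangent
    orientation correlations and persistence length. Analytic scaling
    formulas for channel-like confinement (Odijk deflection, classic and
    extended de Gennes regimes, occupancy threshold, damped orientation
    correlation model) are included together with fitting utilities, and a
    deterministic fixture generator makes every analysis routine testable
    without running dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
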