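Package: StochBS
Title: Stochastic Bulirsch-Stoer Simulation of Chemical Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation of discrete stochastic chemical kinetics for
    mass-action reaction networks. Implements the Stochastic Bulirsch-Stoer
    (SBS) method and its degree-of-advancement variant (SBS-DA), which build
    Romberg/Neville extrapolation of per-step propensity integrals (or
    reaction-count moments) on top of the modified midpoint method, with
    adaptive order and stepsize control and Poisson or hybrid
    Poisson/Gaussian state updates. Also provides the exact Gillespie
    stochastic simulation algorithm (SSA, via compiled code), the adaptive
    Euler tau-leap and the unbiased tau-leap as comparators, benchmark
    reaction systems, a plain-text model format, and analysis tools:
    histogram L1 distances, an efficiency score, weak-order slope
    estimation, truncated chemical-master-equation oracles and exact
    distribution propagation of fixed-step numerical chains.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
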