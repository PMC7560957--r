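Package: fluctinvade
Title: Resident-Invader Dynamics of Similar Strategies in Fluctuating
    Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of invasion dynamics for populations with
    close but distinct strategies in fluctuating environments. Provides a
    general strategy-indexed population model class with explicit environmental
    feedback (ODE-driven and implicitly defined components) and stochastic
    drivers (e.g. Ornstein-Uhlenbeck processes), an Euler-Maruyama simulator,
    ergodic (Birkhoff) averaging for invasion fitness, selection gradients and
    second-order fitness expansions by finite differences with common random
    numbers, classification of invasion outcomes (substitution, coexistence,
    mutual exclusion) from invasion criteria alone, fast-slow validation of the
    averaged dynamics of the invader's relative frequency, pairwise and mutual
    invasibility grids, and a registry of worked example models (chemostat,
    Lotka-Volterra competition, structured SIRS epidemic, prey-predator).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
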