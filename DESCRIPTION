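Package: viabwalk
Title: Viability, Task Switching, and Fall Avoidance of the Simplest Dynamic
    Walker
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the push-off-powered compass walker, the
    simplest actuated model of bipedal walking with definite swing-leg
    dynamics. Implements the hybrid step-to-step Poincare map with impulsive
    push-off actuation, ground-reaction-force and actuation-limit viability
    constraints, grid-based estimation of the viability kernel (the largest
    controlled-invariant region of the post-heel-strike state space) via the
    difference-inclusion image of the step map, numerical continuation of the
    long- and short-period period-1 gait families with period-doubling and
    transcritical bifurcation detection, step-to-step speed regulation toward
    a goal-equivalent target-speed manifold, basin-of-attraction estimation
    for open-loop and speed-regulated walkers, and a hierarchical
    task-switching controller that recovers from large disturbances by
    switching between speed regulators whose basins jointly cover the kernel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
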