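Package: raftmill
Title: Treadmilling Dynamics and Protrusion Growth in Fire Ant Rafts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying collective dynamics of floating fire ant
    rafts. Provides trajectory statistics for self-propelled "free" ants
    (velocities, anomalous mean-square displacement, polar order, persistence
    length, pairwise directional correlation, velocity metric tensor),
    estimators of raft treadmilling rates (structural contraction, bulk exit,
    edge deposition, protrusion growth), a simulator of self-propelled
    particles under strong convex confinement with curvature-weighted wall
    accumulation, and a curvature- and bias-driven boundary-growth model that
    reproduces tether-like protrusion instabilities. A synthetic-data module
    generates active-Brownian trajectories, contracting raft networks and
    biased strip walkers so that every estimator is testable without tracked
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
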