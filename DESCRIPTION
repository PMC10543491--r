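Package: fraudgame
Title: Evolutionary Game Dynamics of Doctor-Patient Health-Insurance Fraud
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the two-population evolutionary game of
    health-insurance fraud between doctors and patients under moral hazard.
    Builds the 2x2 asymmetric payoff matrix from fraud costs, moral-hazard
    coefficients, rewards, penalties, bribery and collusion surplus;
    evaluates expected utilities and the replicator vector field; enumerates
    equilibria and classifies their stability from the Jacobian determinant
    and trace; identifies the parameter regime (unique non-fraud ESS, unique
    fraud ESS, or bistability with an interior saddle); predicts the long-run
    attractor from the saddle position via a quadrilateral-area rule;
    integrates the dynamics with a fixed-step Runge-Kutta scheme; maps basins
    of attraction; and scripts single-parameter sweep experiments over fraud
    cost, moral hazard, penalty, reward and bribery. A seeded scenario
    generator samples parameter sets from each inequality-defined regime.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
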