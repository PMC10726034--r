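Package: mhgame
Title: Differential Games of Mental-Health Protection Policy
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Closed-form analysis of infinite-horizon differential games in
    which a government and a labor union each choose an effort level to
    protect young employees' mental health under one of three policy modes
    (psychological screening, social security provision, strengthened
    training), while their organisational reputation follows
    Nerlove-Arrow goodwill dynamics.  Every (mode, actor) problem reduces
    to a canonical scalar linear-quadratic control problem whose
    Hamilton-Jacobi-Bellman equation admits an affine value function;
    the package computes the feedback equilibrium in closed form,
    verifies it against independent numerical oracles (constant-control
    quadrature, brute-force grid search, HJB residuals, ODE trajectory
    simulation), and reproduces the published mode-comparison study,
    including an audit of benefit coefficients reported in the original
    numerical analysis that disagree with its own propositions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
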