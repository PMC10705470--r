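Package: rsspheroid
Title: Radial-Shell Modeling of Tumor Spheroid Growth and Radiotherapy Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates three-dimensional avascular tumor spheroids with an
    effectively one-dimensional radial-shell model: cell concentrations on
    spherical shells coupled to a quasi-steady-state oxygen profile with a
    self-consistent anoxic core, proliferation limited by free space and
    hypoxia, anoxic cell death, necrotic volume decay and inward transport.
    Radiotherapy is modeled by linear-quadratic survival with an
    Alper-Howard-Flanders oxygen enhancement ratio and time-dependent mitotic
    catastrophe. Includes bounded least-squares calibration of growth curves,
    inference of necrotic radii from outer radii via the closed-form
    steady-state oxygen relation, a synthetic growth-curve generator, and
    parameter transfer to a 3D stochastic cellular automaton through the
    neighborhood mean-distance mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
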