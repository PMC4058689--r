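Package: ffrct
Title: Steady-State Computation of Fractional Flow Reserve in Stenosed Coronary Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates noninvasive fractional flow reserve (FFR) on parametric
    coronary artery trees. Builds an idealized left anterior descending (LAD)
    tree with seven primary branches, inserts concentric stenoses of chosen
    diameter stenosis, length and location, distributes baseline flow among
    outlets by the generalized Murray's law, calibrates per-outlet downstream
    resistance and back pressure from two steady states, applies hyperemic
    resistance scaling, and solves the coupled nonlinear flow network with
    resistance outlet boundary conditions via an underrelaxed outlet-pressure
    fixed point. Segment pressure drops come from integrated Poiseuille laws
    plus a viscous/expansion-loss stenosis model, cross-validated against a
    built-in axisymmetric steady Navier-Stokes finite-difference solver
    (streamfunction-vorticity form) that also reports recirculation metrics.
    Parametric sweeps over stenosis severity, length and location reproduce
    the characteristic dependence of FFR on lesion anatomy.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
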