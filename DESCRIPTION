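Package: frontobstacles
Title: Population Fronts Encountering Growth-Free Obstacles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models of spatial range expansions through heterogeneous habitats
    in which compact growth-free obstacles perturb an advancing population
    front. Implements a constant-speed (eikonal/Huygens) geometric model with
    closed-form front constructions for rhombus- and disk-shaped obstacles and
    a fast-marching first-arrival solver for arbitrary obstacle fields; a
    generalized Fisher-Kolmogorov (FKPP) reaction-diffusion solver with a
    spatially varying growth rate; and a stochastic Eden growth simulator on a
    hexagonal lattice that tracks genotypes and reconstructs the genealogy of
    frontier individuals. Front-shape statistics (indent size, contact angle,
    scaling collapse) quantify the obstacle-induced perturbation and compare
    the engines, including the geometry-enhanced genetic drift produced by
    obstacles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
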