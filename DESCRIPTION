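Package: capshell
Title: Elastic Frustration and Shape Selection in Viral Capsid Self-Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuum-elasticity free energies for the self-assembly of empty
    viral capsids and related protein shells. Implements closed-form scaled
    free energies of formation for spherical caps with and without
    disclinations, ribbons, closed belts and cylinders, both in the
    bending-dominated limit and at arbitrary Foppl-von Karman number; a
    universal phase-diagram engine over the scaled line tension, scaled
    chemical potential and Foppl-von Karman number, with phase-boundary
    tracing; mappings between coarse-grained capsomer interaction parameters,
    dimensional elastic constants and the scaled theory parameters, including
    estimates from experimental capsid mechanics; a Brownian-dynamics
    simulator of anisotropic capsomers (Mie attraction with angular and
    torsion modulation); and shape/defect classification of the assembled
    clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
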