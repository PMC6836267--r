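Package: visualmanifold
Title: Riemannian Geometry of Binocular Perceived Visual Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models three-dimensional perceived visual space as a Riemannian
    manifold whose metric is the Euclidean metric scaled by the inverse square
    of cyclopean distance, the conformal warping implied by the size-distance
    relationship of the eye's optics. Provides the metric tensors in angular,
    tangential and Cartesian bases, Christoffel symbols, Riemann and sectional
    curvature, geodesic spray fields and an adaptive geodesic trajectory
    generator, two-point geodesic shooting, covariant derivatives and parallel
    transport along curves, shape analysis of embedded surfaces (second
    fundamental form, shape operator, principal curvatures), horizontal-plane
    binocular gaze and horopter geometry, simulators for exocentric pointing,
    collinearity and parallelity errors, and a toy place-indexed visuospatial
    memory with vector-bundle morphisms and occlusion filling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
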