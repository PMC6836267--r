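# visualmanifold

Riemannian geometry of binocular perceived visual space, as an R package.

## The scientific problem

The optics of the eye impose a strict size–distance law: the retinal image
of an object shrinks in inverse proportion to its Euclidean distance from
the eye. If perceived size is to follow the same law in every direction
without objects changing their apparent infinitesimal shape, perceived
visual space must contract equally in all three dimensions with distance.
`visualmanifold` models this by equipping the outside world with the
conformally scaled Riemannian metric

    g(q) = (1 / r²) · ḡ,

where `ḡ` is the Euclidean metric and `r` is the Euclidean distance of the
point `q = (r, θ, φ)` (cyclopean spherical coordinates: distance, azimuth,
elevation) from the **egocentre**, the midpoint between the two eyes'
rotation centres. Radial perceived distance becomes logarithmic
(`∫₁^r dr̄/r̄ = ln r`), spheres centred on the egocentre ("visual spheres")
are perceived as flat frontal planes on which size is angle-determined, and
objects moving uniformly in straight lines acquire illusory accelerations.

The package is aimed at researchers in visual perception and computational
neuroscience who want to compute, rather than only cite, the quantitative
consequences of this model: metric inner products and angles, Christoffel
symbols and curvature arrays, geodesic trajectories in the outside world
(the curves perceived as constant-speed straight lines), covariant
derivatives and parallel transport, the shape operator and principal
curvatures of embedded surfaces, the binocular gaze/horopter construction,
predicted errors in exocentric pointing / collinearity / parallelity tasks,
and a toy place-indexed visuospatial memory with vector-bundle morphisms
that fills occlusions between viewpoints.

## Worked example

```r
library(visualmanifold)

q <- cyclopean_point(r = 2, theta = 0, phi = 0)

# the seven nonzero Christoffel symbols, each +-1/r
christoffel_closed_form(q)
#> <christoffel array, tangential basis at (r=2, theta=0, phi=0)>  7 nonzero entries
#>   G^1_11 = -0.5
#>   ...

# curvature component of the r-theta plane: -1/r^4
sectional_curvature(q, c(1, 0, 0), c(0, 1, 0))
#> [1] -0.0625

# perceived (logarithmic) distance of a point 2 m away
perceived_distance(2)
#> [1] 0.6931472

# a circular geodesic: launched tangentially on the 5 m visual sphere it
# orbits at constant metric speed (drift 0 over 20 s)
gt <- integrate_geodesic(c(0, 5, 0), tangent_vector(0, 1, 0, "tangential"),
                         duration = 20)
glance(gt)
#>   n_samples duration gspeed speed_drift truncated
#> 1        41       20    0.2           0 FALSE

# predicted exocentric pointing error for two points 0.4 rad apart at 2 m:
# the pointer is aimed along the connecting geodesic's initial tangent,
# 0.2 rad (half the separation) outside the veridical chord
pointing_error(cyclopean_point(2, -0.2, 0), cyclopean_point(2, 0.2, 0))
#>   task     deviation_rad separation_angle relative_distance
#> 1 pointing          -0.2              0.4                 1

# parallel-transporting a rod between the same two points rotates it by the
# full separation angle: parallelity errors dominate pointing errors
parallelity_error(cyclopean_point(2, -0.2, 0), cyclopean_point(2, 0.2, 0))$deviation_rad
#> [1] 0.4
```

Figure-style geodesic families (spiral families in planes through the
egocentre, great-circle families on visual spheres, the totally geodesic
log-map coordinate grid) are reproduced with `reproduce_figure("fig5a")`
etc., each returning the underlying table and a ggplot. A thin command-line
front end is provided in `exec/vismanifold` (subcommands `gtg`, `curvature`,
`christoffel`, `shape`, `gaze`, `horopter`, `pointing-grid`, `bundle-fill`,
`figures`).

See the methods vignette (`vignettes/visual-space-geometry.Rmd`) for the
model's assumptions, the relation between the two curvature computations the
package exposes, numerical choices, and known limitations.

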