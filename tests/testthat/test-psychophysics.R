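test_that("radially aligned pointer and target give zero deviation", {
  pe <- pointing_error(cyclopean_point(1, 0.5, 0), cyclopean_point(3, 0.5, 0))
  expect_lt(abs(pe$deviation_rad), 1e-8)
  ae <- averaged_pointing_error(cyclopean_point(1, 0.5, 0),
                                cyclopean_point(3, 0.5, 0))
  expect_lt(abs(ae$deviation_rad), 1e-8)
})

test_that("equal-radius pointing deviation equals half the separation angle, aimed outside the chord", {
  # the connecting geodesic is the circular arc; its tangent makes angle
  # sep/2 with the chord, rotated away from the egocentre. For the pointer
  # on the theta < 0 side this is clockwise, i.e. negative by the ccw
  # convention, and the veridical chord lies between the aimed direction
  # and the egocentre.
  for (sep in c(0.2, 0.4, 0.8)) {
    pe <- pointing_error(cyclopean_point(2, -sep / 2, 0),
                         cyclopean_point(2, sep / 2, 0))
    expect_equal(pe$deviation_rad, -sep / 2, tolerance = 1e-6)
  }
})

test_that("pointing deviation grows with separation and is mirror-antisymmetric", {
  devs <- vapply(c(0.2, 0.4, 0.8), function(sep) {
    pointing_error(cyclopean_point(1.5, -sep / 2, 0),
                   cyclopean_point(3, sep / 2, 0))$deviation_rad
  }, numeric(1))
  expect_true(all(diff(abs(devs)) > 0))

  fwd <- pointing_error(cyclopean_point(1.5, -0.3, 0),
                        cyclopean_point(3, 0.3, 0))$deviation_rad
  mir <- pointing_error(cyclopean_point(1.5, 0.3, 0),
                        cyclopean_point(3, -0.3, 0))$deviation_rad
  expect_equal(fwd, -mir, tolerance = 1e-9)
})

test_that("gaze averaging moves the pointing direction closer to veridical", {
  grid <- tidyr::expand_grid(rp = c(1, 2), rt = c(1.5, 3),
                             sep = c(0.3, 0.6))
  for (i in seq_len(nrow(grid))) {
    a <- cyclopean_point(grid$rp[i], -grid$sep[i] / 2, 0)
    b <- cyclopean_point(grid$rt[i], grid$sep[i] / 2, 0)
    single <- abs(pointing_error(a, b)$deviation_rad)
    avg <- abs(averaged_pointing_error(a, b)$deviation_rad)
    expect_lt(avg, single + 1e-12)
  }
  # symmetric equal-radius task: averaging is exactly veridical
  ae <- averaged_pointing_error(cyclopean_point(2, -0.4, 0),
                                cyclopean_point(2, 0.4, 0))
  expect_lt(abs(ae$deviation_rad), 1e-9)
})

test_that("averaged deviation varies with separation and distance ratio, with interaction", {
  g <- pointing_grid(r_pointer = 1.5, r_target = c(1.5, 3, 6),
                     separations = c(0.2, 0.4, 0.8), mode = "averaged")
  m <- matrix(g$deviation_rad, nrow = 3, byrow = TRUE)  # rows: r_target
  # grows in magnitude with separation at fixed unequal ratio
  expect_true(all(diff(abs(m[2, ])) > 0))
  expect_true(all(diff(abs(m[3, ])) > 0))
  # equal radii: exactly compensated
  expect_lt(max(abs(m[1, ])), 1e-9)
  # interaction: the separation effect depends on the distance ratio
  expect_gt(abs((m[3, 3] - m[3, 1]) - (m[2, 3] - m[2, 1])), 1e-3)
})

test_that("collinearity behaves as the averaged pointing strategy", {
  a <- cyclopean_point(1.5, -0.3, 0); b <- cyclopean_point(3, 0.3, 0)
  ce <- collinearity_error(a, b)
  ae <- averaged_pointing_error(a, b)
  expect_identical(ce$task, "collinearity")
  expect_equal(ce$deviation_rad, ae$deviation_rad, tolerance = 1e-12)
})

test_that("parallelity deviation passes through zero, mirrors, and equals the separation at equal radii", {
  tiny <- parallelity_error(cyclopean_point(2, -5e-4, 0),
                            cyclopean_point(2, 5e-4, 0))
  expect_lt(abs(tiny$deviation_rad), 2e-3)

  pl <- parallelity_error(cyclopean_point(2, -0.4, 0),
                          cyclopean_point(2, 0.4, 0))
  # in-plane transport rotates every vector by the angular advance
  expect_equal(pl$deviation_rad, 0.8, tolerance = 1e-5)
  mir <- parallelity_error(cyclopean_point(2, 0.4, 0),
                           cyclopean_point(2, -0.4, 0))
  expect_equal(pl$deviation_rad, -mir$deviation_rad, tolerance = 1e-5)
  # independent of the rod orientation (2D isometry)
  pl2 <- parallelity_error(cyclopean_point(2, -0.4, 0),
                           cyclopean_point(2, 0.4, 0), rod_angle = 0.3)
  expect_equal(pl$deviation_rad, pl2$deviation_rad, tolerance = 1e-6)
})

test_that("parallelity deviations dominate averaged-pointing deviations grid-wise", {
  seps <- c(0.2, 0.4, 0.8)
  par_dev <- abs(pointing_grid(r_pointer = c(1, 2), r_target = c(1, 2),
                               separations = seps,
                               mode = "parallelity")$deviation_rad)
  avg_dev <- abs(pointing_grid(r_pointer = c(1, 2), r_target = c(1, 2),
                               separations = seps,
                               mode = "averaged")$deviation_rad)
  expect_gt(stats::median(par_dev), stats::median(avg_dev))
})

test_that("deviation surfaces are invariant under rotation about the egocentre", {
  base <- pointing_error(cyclopean_point(1.5, -0.3, 0),
                         cyclopean_point(3, 0.3, 0))$deviation_rad
  rot <- pointing_error(cyclopean_point(1.5, -0.3 + 0.9, 0),
                        cyclopean_point(3, 0.3 + 0.9, 0))$deviation_rad
  expect_equal(base, rot, tolerance = 1e-9)
})

test_that("holonomy around a closed geodesic quadrilateral on a visual sphere equals its area", {
  # vertices on the r = 1 visual sphere; sides are great-circle geodesics.
  # Transport around the loop rotates tangent vectors by the enclosed
  # spherical area (the sphere factor carries all the ambient curvature).
  verts <- list(cyclopean_point(1, 0, 0), cyclopean_point(1, 0.8, 0),
                cyclopean_point(1, 0.8, 0.6), cyclopean_point(1, 0, 0.6))
  v <- convert_basis(tangent_vector(0, 1, 0, "tangential"), verts[[1]],
                     "angular")
  for (i in 1:4) {
    a <- verts[[i]]; b <- verts[[if (i == 4) 1 else i + 1]]
    geo <- two_point_geodesic(a, b, cadence = 0.02)
    pt <- parallel_transport(geo, v)
    n <- nrow(pt)
    qb <- cyclopean_point(geo$r[n], geo$theta[n], geo$phi[n])
    v <- tangent_vector(pt$g1[n], pt$g2[n], pt$g3[n], "angular")
    attr(v, "at") <- qb
  }
  v0c <- convert_basis(tangent_vector(0, 1, 0, "tangential"), verts[[1]],
                       "cartesian")$v
  vTc <- convert_basis(v, verts[[1]], "cartesian")$v
  hol <- acos(min(1, max(-1, sum(v0c * vTc) /
                           sqrt(sum(v0c^2) * sum(vTc^2)))))
  # oracle: the enclosed spherical area is the polygon's angular excess
  uv <- lapply(verts, function(q) as.numeric(as_cartesian(q)) / q$r)
  interior_angle <- function(prev, at, nxt) {
    ta <- prev - sum(prev * at) * at
    tb <- nxt - sum(nxt * at) * at
    acos(sum(ta * tb) / sqrt(sum(ta^2) * sum(tb^2)))
  }
  angles <- vapply(1:4, function(i) {
    interior_angle(uv[[if (i == 1) 4 else i - 1]], uv[[i]],
                   uv[[if (i == 4) 1 else i + 1]])
  }, numeric(1))
  area <- sum(angles) - 2 * pi
  expect_gt(hol, 0.05)
  expect_equal(hol, area, tolerance = 1e-4)
})

test_that("egocentric pointing from just off the origin is exact", {
  pe <- pointing_error(cyclopean_point(1e-3, 0.7, 0),
                       cyclopean_point(2, 0.7, 0))
  expect_lt(abs(pe$deviation_rad), 1e-6)
})
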