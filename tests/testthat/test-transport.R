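test_that("the covariant acceleration vanishes along geodesics", {
  tr <- integrate_geodesic(cyclopean_point(2, 0.3, 0.1),
                           tangent_vector(0.4, 0.6, -0.2, "angular"),
                           duration = 4, cadence = 0.02)
  cd <- covariant_derivative_along(tr)
  inner <- cd[2:(nrow(cd) - 1), ]
  expect_lt(max(inner$gnorm), 1e-4)
})

test_that("uniform straight-line approach shows the illusory radial acceleration", {
  # constant-Euclidean-speed radial approach: rdot = -1 along a fixed ray
  tt <- seq(0, 1.5, by = 0.01)
  curve <- curve_tbl(tt, r = 3 - tt, theta = rep(0.7, length(tt)),
                     phi = rep(0, length(tt)),
                     dr = rep(-1, length(tt)), dtheta = rep(0, length(tt)),
                     dphi = rep(0, length(tt)))
  cd <- covariant_derivative_along(curve)
  # perceived acceleration = -f2 = (-rdot^2/r, 0, 0) = -1/r(t) radially
  expect_lt(max(abs(cd$d1 + 1 / curve$r)), 1e-8)
  expect_lt(max(abs(cd$d2)), 1e-10)
  expect_lt(max(abs(cd$d3)), 1e-10)
})

test_that("the covariant derivative is linear and vanishes on the zero field", {
  tr <- integrate_geodesic(cyclopean_point(2, 0, 0),
                           tangent_vector(0.2, 0.5, 0.1, "angular"),
                           duration = 2, cadence = 0.1)
  z <- covariant_derivative_along(tr, field = matrix(0, nrow(tr), 3))
  expect_equal(max(abs(c(z$d1, z$d2, z$d3))), 0)
  expect_error(covariant_derivative_along(tr[1:2, ]), "3 samples")
})

test_that("parallel transport is isometric and keeps geodesic tangents tangent", {
  tr <- integrate_geodesic(cyclopean_point(1.5, -0.2, 0.1),
                           tangent_vector(0.3, 0.4, 0.2, "angular"),
                           duration = 4, cadence = 0.02)
  # transporting the initial velocity must track the velocity itself
  v0 <- tangent_vector(tr$dr[1], tr$dtheta[1], tr$dphi[1], "angular")
  pt <- parallel_transport(tr, v0)
  worst <- 0
  for (i in seq_len(nrow(tr))) {
    q <- cyclopean_point(tr$r[i], tr$theta[i], tr$phi[i])
    diffv <- tangent_vector(pt$g1[i] - tr$dr[i], pt$g2[i] - tr$dtheta[i],
                            pt$g3[i] - tr$dphi[i], "angular")
    worst <- max(worst, metric_norm(q, diffv))
  }
  expect_lt(worst, 1e-5)
  expect_lt(attr(pt, "isometry_drift"), 1e-5)
})

test_that("transport along a radial geodesic preserves the frame inner products", {
  tr <- integrate_geodesic(cyclopean_point(1, 0.4, 0),
                           tangent_vector(1, 0, 0, "tangential"),
                           duration = 10, cadence = 0.05)
  # eta: radial unit; xi: circumferential (Killing) direction
  eta0 <- convert_basis(tangent_vector(1, 0, 0, "tangential"),
                        cyclopean_point(1, 0.4, 0), "angular")
  xi0 <- convert_basis(tangent_vector(0, 1, 0, "tangential"),
                       cyclopean_point(1, 0.4, 0), "angular")
  pe <- parallel_transport(tr, eta0)
  px <- parallel_transport(tr, xi0)
  q0 <- cyclopean_point(tr$r[1], tr$theta[1], tr$phi[1])
  ips0 <- c(metric_inner(q0, eta0, eta0), metric_inner(q0, xi0, xi0),
            metric_inner(q0, eta0, xi0))
  n <- nrow(tr)
  qn <- cyclopean_point(tr$r[n], tr$theta[n], tr$phi[n])
  etaT <- tangent_vector(pe$g1[n], pe$g2[n], pe$g3[n], "angular")
  xiT <- tangent_vector(px$g1[n], px$g2[n], px$g3[n], "angular")
  ipsT <- c(metric_inner(qn, etaT, etaT), metric_inner(qn, xiT, xiT),
            metric_inner(qn, etaT, xiT))
  expect_lt(max(abs(ipsT - ips0)), 1e-5)
})

test_that("metric length of circular arcs equals the subtended angle at every radius", {
  for (r in c(1, 2, 10)) {
    dth <- 0.8
    tt <- seq(0, dth, length.out = 401)
    arc <- curve_tbl(tt, r = rep(r, 401), theta = tt, phi = rep(0, 401),
                     dr = rep(0, 401), dtheta = rep(1, 401),
                     dphi = rep(0, 401))
    expect_equal(curve_length(arc), dth, tolerance = 1e-9)
  }
})

test_that("metric length of a radial segment is the log of the distance ratio", {
  for (R in c(2, 10, 50)) {
    tt <- seq(0, 1, length.out = 2001)
    seg <- curve_tbl(tt, r = 1 + (R - 1) * tt, theta = rep(0, 2001),
                     phi = rep(0, 2001), dr = rep(R - 1, 2001),
                     dtheta = rep(0, 2001), dphi = rep(0, 2001))
    expect_equal(curve_length(seg), log(R), tolerance = 1e-6)
  }
  tt <- seq(0, 1, length.out = 11)
  seg <- curve_tbl(tt, 1 + tt, rep(0, 11), rep(0, 11), rep(1, 11),
                   rep(0, 11), rep(0, 11))
  expect_identical(curve_length(seg, t_start = 0.3, t_end = 0.3), 0)
})

test_that("boundary curvature vanishes on geodesics and matches the log-chart oracle", {
  # circular geodesic at unit metric speed: kappa = 0
  dth <- 1.2
  tt <- seq(0, dth, length.out = 301)
  arc <- curve_tbl(tt, r = rep(3, 301), theta = tt, phi = rep(0, 301),
                   dr = rep(0, 301), dtheta = rep(1, 301), dphi = rep(0, 301))
  bc <- boundary_curvature(arc)
  expect_lt(max(bc$kappa), 1e-4)

  # Euclidean circle not centred on the egocentre, unit metric speed:
  # positive, varying curvature, equal to the Euclidean curvature of the
  # curve's image in the isometric (log r, theta) chart of the plane
  ang <- seq(0, 2 * pi, length.out = 2001)[-2001]
  cx <- 2 + 0.6 * cos(ang); cy <- 0.6 * sin(ang)
  rr <- sqrt(cx^2 + cy^2); th <- atan2(cy, cx)
  seg <- which(ang < 2.0)  # an open arc, away from wrap-around
  crv <- curve_tbl(ang[seg], rr[seg], th[seg], rep(0, length(seg)))
  crv_u <- unit_speed_reparameterize(crv, n = 801)
  suppressWarnings(bc <- boundary_curvature(crv_u))
  expect_true(all(bc$kappa > 0))
  expect_gt(max(bc$kappa) - min(bc$kappa), 0.05)  # genuinely varying

  kap_chart <- chart_curvature(log(crv_u$r), crv_u$theta)
  idx <- 10:(nrow(crv_u) - 10)
  expect_lt(max(abs(bc$kappa[match(idx, 2:(nrow(crv_u) - 1))] -
                      kap_chart[idx])), 5e-3)
})
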