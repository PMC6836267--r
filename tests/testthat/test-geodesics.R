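test_that("integrated geodesics match the closed-form flow", {
  cases <- list(
    list(q0 = cyclopean_point(1, pi / 2, 0), v = c(1, 0, 0), dur = 5),      # radial out
    list(q0 = cyclopean_point(5, pi / 2, 0), v = c(0, 0.2, 0), dur = 20),   # circle
    list(q0 = cyclopean_point(5, pi / 2, 0), v = c(0, 0, 0.2), dur = 20),   # great circle
    list(q0 = cyclopean_point(2, 0.4, 0.15), v = c(0.3, 0.5, -0.2), dur = 5) # spiral
  )
  for (cs in cases) {
    tr <- integrate_geodesic(cs$q0, tangent_vector(cs$v[1], cs$v[2], cs$v[3],
                                                   "angular"),
                             duration = cs$dur, cadence = 0.5)
    ref <- exact_geodesic_xyz(cs$q0, cs$v, tr$t)
    expect_lt(max(abs(cbind(tr$x, tr$y, tr$z) - ref)), 1e-6)
    expect_lt(attr(tr, "diagnostics")$speed_drift, 1e-6)
  }
})

test_that("radial launches stay on the axis and accelerate outward", {
  tr <- integrate_geodesic(c(0, 1, 0), tangent_vector(0, 1, 0, "cartesian"),
                           duration = 5, cadence = 0.25)
  expect_lt(max(abs(tr$x)), 1e-10)
  expect_lt(max(abs(tr$z)), 1e-10)
  expect_true(all(diff(tr$r) > 0))
  expect_true(all(diff(diff(tr$r)) > 0))  # outward Euclidean acceleration
})

test_that("circular and great-circle launches stay on their visual sphere", {
  circ <- integrate_geodesic(c(0, 5, 0), tangent_vector(0, 1, 0, "tangential"),
                             duration = 20, cadence = 0.5)
  expect_lt(max(abs(circ$r - 5)), 1e-6)
  expect_lt(max(abs(circ$z)), 1e-8)

  great <- integrate_geodesic(c(0, 5, 0), tangent_vector(0, 0, 1, "tangential"),
                              duration = 20, cadence = 0.5)
  expect_lt(max(abs(great$r - 5)), 1e-5)
})

test_that("planes through the egocentre are totally geodesic", {
  fam <- geodesic_family(c(0, 1, 0), c(1, 0, 0), c(0, 1, 0),
                         n_directions = 36, duration = 2, cadence = 0.25)
  expect_identical(length(unique(fam$traj_id)), 36L)
  expect_lt(max(abs(fam$z)), 1e-8)

  # a tilted plane through the egocentre, out-of-plane excursion via its normal
  e2 <- c(0, 1, 1) / sqrt(2)
  fam2 <- geodesic_family(cartesian_point(0, 3 / sqrt(2), 3 / sqrt(2)),
                          c(1, 0, 0), e2,
                          n_directions = 12, duration = 2, cadence = 0.25)
  oop <- abs(-fam2$y + fam2$z) / sqrt(2)
  expect_lt(max(oop), 1e-8)
})

test_that("normal-plane launches sweep the visual sphere; tilted planes do neither", {
  q0 <- cartesian_point(0, 5 / sqrt(2), 5 / sqrt(2))
  fam <- geodesic_family(q0, c(1, 0, 0), c(0, -1, 1) / sqrt(2),
                         n_directions = 12, duration = 10, cadence = 0.5,
                         speed = "euclidean")
  expect_lt(max(abs(fam$r - 5)) / 5, 1e-6)

  tilted <- geodesic_family(q0, c(1, 0, 0), c(0, 0, 1),
                            n_directions = 12, duration = 6, cadence = 0.5,
                            speed = "euclidean")
  expect_gt(max(abs(tilted$r - 5)) / 5, 1e-3)           # not sphere-confined
  oop <- abs(tilted$y - 5 / sqrt(2))                    # xz-plane through q0
  expect_gt(max(oop), 1e-3)                             # not plane-confined
})

test_that("the geodesic pattern is rotation equivariant", {
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  v0 <- c(0.5, 0.8, 0.2)
  g1 <- integrate_geodesic(c(0, 2, 0), v0, duration = 3, cadence = 0.5)
  g2 <- integrate_geodesic(as.numeric(R %*% c(0, 2, 0)),
                           as.numeric(R %*% v0), duration = 3, cadence = 0.5)
  p1r <- as.matrix(g1[, c("x", "y", "z")]) %*% t(R)
  expect_lt(max(abs(p1r - as.matrix(g2[, c("x", "y", "z")]))), 1e-8)
})

test_that("neighbouring 1 m/s geodesics separate less when launched further away", {
  terminal_sep <- function(r0) {
    q <- cartesian_point(0, r0, 0)
    fam <- geodesic_family(q, c(1, 0, 0), c(0, 1, 0), n_directions = 36,
                           duration = 2, cadence = 2, speed = "euclidean")
    a <- fam[fam$traj_id == 1 & fam$t == 2, c("x", "y", "z")]
    b <- fam[fam$traj_id == 2 & fam$t == 2, c("x", "y", "z")]  # 10 deg apart
    sqrt(sum((a - b)^2))
  }
  expect_gt(terminal_sep(1), terminal_sep(5))
})

test_that("trajectories are truncated with a flag at the radial floor and the poles", {
  inward <- integrate_geodesic(c(0, 2, 0),
                               tangent_vector(-1, 0, 0, "tangential"),
                               duration = 30, cadence = 0.5)
  expect_true(attr(inward, "truncated"))
  expect_lt(min(inward$r), 1e-3)

  over_pole <- integrate_geodesic(c(0, 5, 0),
                                  tangent_vector(0, 0, 1, "tangential"),
                                  duration = 40, cadence = 0.5)
  expect_true(attr(over_pole, "truncated"))
  expect_gt(max(abs(over_pole$phi)), pi / 2 - 1e-3)
})

test_that("two-point shooting recovers radial, spherical and planar connections", {
  # radial pair: the straight segment
  tr <- two_point_geodesic(cyclopean_point(1, 0.5, 0.2),
                           cyclopean_point(3, 0.5, 0.2))
  expect_lt(max(abs(tr$theta - 0.5)), 1e-9)
  expect_lt(max(abs(tr$phi - 0.2)), 1e-9)
  expect_lt(attr(tr, "endpoint_error"), 1e-6 * 3)

  # same visual sphere: the great-circle arc, against the analytic circle
  qA <- cyclopean_point(4, 0.2, 0.1)
  qB <- cyclopean_point(4, 1.1, 0.5)
  tr <- two_point_geodesic(qA, qB, cadence = 0.05)
  expect_lt(max(abs(tr$r - 4)) / 4, 1e-8)
  v0 <- c(tr$dr[1], tr$dtheta[1], tr$dphi[1])
  ref <- exact_geodesic_xyz(qA, v0, tr$t)
  expect_lt(max(abs(cbind(tr$x, tr$y, tr$z) - ref)), 1e-6)

  # horizontal-plane pair: plane-confined, endpoint within tolerance
  tr <- two_point_geodesic(cyclopean_point(2, 0, 0), cyclopean_point(2, 1, 0))
  expect_lt(attr(tr, "endpoint_error"), 1e-6 * 2)
  expect_lt(max(abs(tr$z)), 1e-8)

  expect_error(two_point_geodesic(cyclopean_point(2, 0, 0),
                                  cyclopean_point(2, 0, 0)), "distinct")
})

test_that("diametric visual-sphere endpoints are flagged as ambiguous", {
  tr <- two_point_geodesic(cyclopean_point(3, 0.4, 0),
                           cartesian_to_spherical(-as.numeric(
                             as_cartesian(cyclopean_point(3, 0.4, 0)))))
  expect_true(attr(tr, "multiplicity"))
  expect_lt(attr(tr, "endpoint_error"), 1e-6 * 3)
})
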