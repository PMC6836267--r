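test_that("spherical/Cartesian conversion matches the convention and round-trips", {
  p <- spherical_to_cartesian(cyclopean_point(1, 0, 0))
  expect_equal(as.numeric(p), c(1, 0, 0), tolerance = 1e-14)

  p <- spherical_to_cartesian(cyclopean_point(5, pi / 2, 0))
  expect_equal(as.numeric(p), c(0, 5, 0), tolerance = 1e-12)

  p <- spherical_to_cartesian(cyclopean_point(5, pi / 2, pi / 4))
  expect_equal(round(as.numeric(p), 2), c(0, 3.54, 3.54))
  expect_equal(as.numeric(p)[2], 5 / sqrt(2), tolerance = 1e-12)

  set.seed(11)
  for (i in 1:100) {
    q <- random_interior_point()
    q2 <- cartesian_to_spherical(spherical_to_cartesian(q))
    expect_lt(abs(q2$r - q$r) / q$r, 1e-12)
    expect_lt(abs(q2$phi - q$phi), 1e-12)
    dth <- (q2$theta - q$theta) %% (2 * pi)
    expect_lt(min(dth, 2 * pi - dth), 1e-12)
  }

  expect_error(cartesian_to_spherical(c(0, 0, 0)), "undefined")
  expect_error(cyclopean_point(-1, 0, 0), "positive")
  expect_error(cyclopean_point(1, 0, pi / 2), "poles")
})

test_that("metric matrices take the stated form in all three bases", {
  expect_equal(metric_matrix(cyclopean_point(1, 0.3, 0), "angular")$m, diag(3))
  expect_equal(metric_matrix(cyclopean_point(2, 0, 0), "tangential")$m,
               diag(3) * 0.25)
  expect_equal(metric_matrix(cyclopean_point(2, 1, pi / 3), "angular")$m,
               diag(c(0.25, 0.25, 1)), tolerance = 1e-14)

  expect_equal(euclidean_metric_matrix(cyclopean_point(3, 0, 0), "angular")$m,
               diag(c(1, 9, 9)))
  expect_equal(euclidean_metric_matrix(cyclopean_point(7, 2, 0.9),
                                       "tangential")$m, diag(3))
  eg <- euclidean_metric_matrix(cyclopean_point(2, 0, pi / 3), "angular")$m
  expect_equal(eg, diag(c(1, 1, 4)), tolerance = 1e-14)
  expect_equal(det(eg), 2^4 * cos(pi / 3)^2, tolerance = 1e-12)

  # conformal relation g = (1/r^2) g_euclid in every basis
  set.seed(21)
  for (i in 1:25) {
    q <- random_interior_point()
    for (b in c("angular", "tangential", "cartesian")) {
      expect_equal(metric_matrix(q, b)$m,
                   euclidean_metric_matrix(q, b)$m / q$r^2,
                   tolerance = 1e-12)
    }
    expect_equal(det(metric_matrix(q, "angular")$m), cos(q$phi)^2 / q$r^2,
                 tolerance = 1e-10)
  }
})

test_that("inner products, norms and angles behave conformally", {
  q <- cyclopean_point(3, 0.7, 0)
  a <- metric_angle(q, tangent_vector(1, 0, 0, "tangential"),
                    tangent_vector(0, 1, 0, "tangential"))
  expect_equal(a, pi / 2, tolerance = 1e-14)

  v <- tangent_vector(0.4, -0.8, 0.1, "angular")
  expect_equal(metric_angle(q, v, v), 0, tolerance = 1e-7)

  expect_equal(metric_norm(cyclopean_point(2, 0, 0),
                           tangent_vector(1, 0, 0, "tangential")), 0.5)

  expect_error(metric_angle(q, tangent_vector(0, 0, 0, "angular"), v),
               "zero-length")

  set.seed(31)
  worst_angle <- 0; worst_scale <- 0
  for (i in 1:500) {
    q <- random_interior_point()
    v <- tangent_vector(rnorm(1), rnorm(1), rnorm(1), "angular")
    w <- tangent_vector(rnorm(1), rnorm(1), rnorm(1), "tangential")
    worst_angle <- max(worst_angle,
                       abs(metric_angle(q, v, w) -
                             metric_angle(q, v, w, euclidean = TRUE)))
    worst_scale <- max(worst_scale,
                       abs(metric_norm(q, v) -
                             metric_norm(q, v, euclidean = TRUE) / q$r))
  }
  expect_lt(worst_angle, 1e-10)
  expect_lt(worst_scale, 1e-10)
})

test_that("metric inner products are invariant under rotations about the egocentre", {
  rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                                0, 0, 1), 3, 3)
  rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a),
                                0, -sin(a), cos(a)), 3, 3)
  set.seed(41)
  worst <- 0
  for (i in 1:50) {
    q <- random_interior_point()
    v <- rnorm(3); w <- rnorm(3)
    R <- rot_z(runif(1, -pi, pi)) %*% rot_x(runif(1, -0.6, 0.6))
    qx <- as.numeric(as_cartesian(q))
    qr_pt <- tryCatch(cartesian_to_spherical(as.numeric(R %*% qx)),
                      error = function(e) NULL)
    if (is.null(qr_pt)) next  # rotated into the polar band; draw skipped
    ip0 <- metric_inner(q, tangent_vector(v[1], v[2], v[3], "cartesian"),
                        tangent_vector(w[1], w[2], w[3], "cartesian"))
    vr <- as.numeric(R %*% v); wr <- as.numeric(R %*% w)
    ip1 <- metric_inner(qr_pt, tangent_vector(vr[1], vr[2], vr[3], "cartesian"),
                        tangent_vector(wr[1], wr[2], wr[3], "cartesian"))
    worst <- max(worst, abs(ip1 - ip0))
  }
  expect_lt(worst, 1e-10)
})

test_that("angular and tangential velocity components interconvert exactly", {
  q <- cyclopean_point(2, 1.1, 0)
  v <- convert_basis(tangent_vector(0, 1, 0, "angular"), q, "tangential")
  expect_equal(v$v, c(0, 2, 0))

  q <- cyclopean_point(5, -0.2, pi / 3)
  v <- convert_basis(tangent_vector(1, 0, 2, "angular"), q, "tangential")
  expect_equal(v$v, c(1, 0, 10), tolerance = 1e-14)

  set.seed(51)
  worst <- 0
  for (i in 1:100) {
    q <- random_interior_point()
    v <- tangent_vector(rnorm(1), rnorm(1), rnorm(1), "angular")
    vt <- convert_basis(v, q, "tangential")
    vc <- convert_basis(v, q, "cartesian")
    n0 <- metric_norm(q, v)
    worst <- max(worst, abs(metric_norm(q, vt) - n0),
                 abs(metric_norm(q, vc) - n0),
                 max(abs(convert_basis(vt, q, "angular")$v - v$v)),
                 max(abs(convert_basis(vc, q, "angular")$v - v$v)))
  }
  expect_lt(worst, 1e-10)
})

test_that("perceived distance is the logarithm of Euclidean distance", {
  expect_equal(perceived_distance(1), 0)
  expect_equal(perceived_distance(exp(1)), 1)
  expect_equal(perceived_distance(10), log(10), tolerance = 1e-14)
  expect_lt(perceived_distance(0.5), 0)  # inside the 1 m shell

  for (rr in c(1, 1.5, 10, 42, 100)) {
    expect_lt(abs(perceived_distance(rr, "quadrature") - log(rr)), 1e-8)
  }
  expect_equal(perceived_distance_inverse(perceived_distance(7.3)), 7.3,
               tolerance = 1e-12)
  expect_error(perceived_distance(0), "positive")
  expect_error(perceived_distance(-2), "positive")
})

test_that("point records serialize with the documented column order", {
  q <- cyclopean_point(2, 0.3, -0.1)
  rec <- point_record(q, tangent_vector(1, 2, 3, "tangential"))
  expect_identical(names(rec),
                   c("r", "theta", "phi", "basis", "c1", "c2", "c3"))
  expect_identical(rec$basis, "tangential")
})
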