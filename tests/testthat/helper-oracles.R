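# Independent oracles used across the suite. These re-derive expected
# behaviour from first principles, separately from the package code paths
# they check.

# Closed-form geodesic flow. Writing u = log r, the metric
# diag(1/r^2, cos^2 phi, 1) becomes du^2 + (unit-sphere metric), a product:
# geodesics run linearly in u while the direction vector follows a great
# circle at constant angular rate. This gives exact Cartesian positions for
# any initial condition.
exact_geodesic_xyz <- function(q0, v0_angular, times) {
  r0 <- q0$r; th <- q0$theta; ph <- q0$phi
  s0 <- c(cos(ph) * cos(th), cos(ph) * sin(th), sin(ph))
  eth <- c(-sin(th), cos(th), 0)
  eph <- c(-sin(ph) * cos(th), -sin(ph) * sin(th), cos(ph))
  sdot <- cos(ph) * v0_angular[2] * eth + v0_angular[3] * eph
  a <- v0_angular[1] / r0                 # du/dt
  om <- sqrt(sum(sdot^2))                 # great-circle rate
  t(vapply(times, function(t) {
    s <- if (om < 1e-15) s0 else cos(om * t) * s0 + sin(om * t) * sdot / om
    exp(log(r0) + a * t) * s
  }, numeric(3)))
}

# Brute-force curvature components from finite differences of
# finite-difference Christoffel symbols (independent of the package's
# analytic derivative route).
brute_force_riemann_up <- function(q, h = 1e-4) {
  gam_at <- function(x) {
    christoffel_numeric(cyclopean_point(x[1], x[2], x[3]),
                        basis = "tangential")$gamma
  }
  x0 <- c(q$r, q$theta, q$phi)
  g0 <- gam_at(x0)
  dgam <- array(0, c(3, 3, 3, 3))
  for (d in 1:3) {
    xp <- x0; xm <- x0
    xp[d] <- xp[d] + h; xm[d] <- xm[d] - h
    dgam[, , , d] <- (gam_at(xp) - gam_at(xm)) / (2 * h)
  }
  up <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    s <- dgam[l, j, k, i] - dgam[l, k, i, j]
    for (m in 1:3) {
      s <- s + g0[m, j, k] * g0[l, m, i] - g0[m, k, i] * g0[l, m, j]
    }
    up[i, j, k, l] <- s
  }
  up
}

random_interior_point <- function() {
  cyclopean_point(stats::runif(1, 0.5, 6),
                  stats::runif(1, -pi, pi),
                  stats::runif(1, -1.2, 1.2))
}

fit_circle_xy <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  sol <- qr.solve(A, x^2 + y^2)
  list(centre = sol[1:2], radius = sqrt(sol[3] + sol[1]^2 + sol[2]^2))
}

# Geodesic integration using the tangential-velocity spray representation.
# The tangential components are the frame components of the Cartesian
# acceleration (the spray is non-tensorial: the same geodesics, a different
# coordinate expression), so the natural integrator for this representation
# works in the Cartesian chart: xddot = frame(q) . f2_tangential(q, v) with
# v the frame components of xdot.
integrate_geodesic_tangential <- function(q0, v0_tangential, duration,
                                          cadence = 0.1) {
  frame_cols <- function(th, ph) {
    cbind(c(cos(ph) * cos(th), cos(ph) * sin(th), sin(ph)),
          c(-sin(th), cos(th), 0),
          c(-sin(ph) * cos(th), -sin(ph) * sin(th), cos(ph)))
  }
  x0 <- as.numeric(spherical_to_cartesian(q0))
  F0 <- frame_cols(q0$theta, q0$phi)
  xdot0 <- as.numeric(F0 %*% v0_tangential)
  rhs <- function(t, y, parms) {
    x <- y[1:3]; xd <- y[4:6]
    q <- cartesian_to_spherical(x)
    Fm <- frame_cols(q$theta, q$phi)
    v <- as.numeric(crossprod(Fm, xd))
    list(c(xd, as.numeric(Fm %*% spray_f2_tangential(q, v)$v)))
  }
  times <- seq(0, duration, by = cadence)
  out <- deSolve::lsoda(c(x0, xdot0), times, rhs, NULL,
                        rtol = 1e-11, atol = 1e-13)
  data.frame(t = out[, 1], x = out[, 2], y = out[, 3], z = out[, 4])
}

# Euclidean curvature of a planar curve given dense samples (three-point
# circumcircle estimate), used as the log-chart oracle for perceived
# boundary curvature in the horizontal plane.
chart_curvature <- function(u, v) {
  n <- length(u)
  kap <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    a <- c(u[i - 1], v[i - 1]); b <- c(u[i], v[i]); cc <- c(u[i + 1], v[i + 1])
    ab <- b - a; bc <- cc - b; ac <- cc - a
    cross <- ab[1] * bc[2] - ab[2] * bc[1]
    denom <- sqrt(sum(ab^2)) * sqrt(sum(bc^2)) * sqrt(sum(ac^2))
    kap[i] <- 2 * abs(cross) / denom
  }
  kap
}

# Count symmetry-distinct nonzero lowered curvature components.
distinct_nonzero_orbits <- function(down, r, eps = 1e-9) {
  seen <- character(0)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    if (abs(down[i, j, k, l]) * r^4 < eps) next
    # canonical representative of the symmetry orbit
    p1 <- c(i, j); p2 <- c(k, l)
    c1 <- c(sort(p1), sort(p2))
    c2 <- c(sort(p2), sort(p1))
    key <- paste(pmin(c1, c2)[1], pmax(c1, c2)[1],
                 paste(sort(c(paste(sort(p1), collapse = ""),
                              paste(sort(p2), collapse = ""))), collapse = "|"))
    seen <- union(seen, key)
  }
  length(seen)
}
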