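geodesic_rhs <- function(t, y, parms) {
  # y = (r, theta, phi, rdot, thetadot, phidot)
  f <- spray_f2_angular_raw(y[1], y[3], y[4:6])
  list(c(y[4], y[5], y[6], f))
}

geodesic_root <- function(t, y, parms) {
  c(y[1] - parms$r_floor, pi / 2 - parms$pole_eps - abs(y[3]))
}

metric_speed_angular <- function(r, phi, dr, dtheta, dphi) {
  sqrt((dr / r)^2 + (cos(phi) * dtheta)^2 + dphi^2)
}

finish_trajectory <- function(out, q0, v0_ang, duration, diagnostics = list()) {
  tb <- tibble::as_tibble(as.data.frame(out))
  names(tb) <- c("t", "r", "theta", "phi", "dr", "dtheta", "dphi")
  tb$x <- tb$r * cos(tb$phi) * cos(tb$theta)
  tb$y <- tb$r * cos(tb$phi) * sin(tb$theta)
  tb$z <- tb$r * sin(tb$phi)
  tb$gspeed <- metric_speed_angular(tb$r, tb$phi, tb$dr, tb$dtheta, tb$dphi)
  truncated <- max(tb$t) < duration - 1e-9
  drift <- if (tb$gspeed[1] > 0) {
    max(abs(tb$gspeed - tb$gspeed[1])) / tb$gspeed[1]
  } else 0
  structure(tb,
            class = c("geodesic_trajectory", class(tb)),
            q0 = q0, v0 = v0_ang,
            truncated = truncated,
            diagnostics = c(diagnostics, list(speed_drift = drift)))
}

#' Integrate a geodesic of the perceived visual manifold
#'
#' Solves the second-order geodesic system `qddot = f2(q, qdot)` in the
#' spherical chart with the angular spray ([spray_f2_angular()]), using an
#' adaptive solver with root-stopping: the integration terminates with a
#' `truncated` flag (not a silent failure) if the trajectory reaches the
#' polar exclusion band or the radial floor.
#'
#' Geodesics of this metric are radial lines (perceived as straight and
#' traversed with apparent acceleration), constant-speed circles and great
#' circles on spheres centred at the egocentre, and logarithmic spirals in
#' planes through the egocentre. The metric speed `|qdot|_g` is constant
#' along the solution; its relative drift is recorded as an integrator
#' diagnostic.
#'
#' @param q0 Initial point: a [cyclopean_point()], [cartesian_point()] or
#'   numeric xyz.
#' @param v0 Initial velocity: a [tangent_vector()] (any basis) or numeric
#'   length-3 taken as Cartesian components.
#' @param duration Integration time, seconds.
#' @param cadence Output sampling interval, seconds (default 0.5 s, the
#'   dot spacing used in the trajectory figures).
#' @param rtol,atol Solver tolerances.
#' @param r_floor Radial floor, metres.
#' @param pole_eps Polar exclusion half-width, radians.
#' @return A tibble of class `geodesic_trajectory` with columns
#'   `t, r, theta, phi, dr, dtheta, dphi, x, y, z, gspeed`, plus
#'   attributes `q0`, `v0` (angular), `truncated` and `diagnostics`.
#' @export
#' @examples
#' gt <- integrate_geodesic(c(0, 5, 0), tangent_vector(0, 1, 0, "tangential"),
#'                          duration = 2)
#' range(gt$r)  # circular geodesic: stays at radius 5
integrate_geodesic <- function(q0, v0, duration, cadence = 0.5,
                               rtol = 1e-11, atol = 1e-13,
                               r_floor = 1e-6, pole_eps = 1e-6) {
  q0 <- as_cyclopean(q0)
  if (!inherits(v0, "tangent_vector")) {
    stopifnot(is.numeric(v0), length(v0) == 3L)
    v0 <- tangent_vector(v0[1], v0[2], v0[3], "cartesian")
  }
  v0a <- convert_basis(v0, q0, "angular")
  times <- unique(c(seq(0, duration, by = cadence), duration))
  y0 <- c(q0$r, q0$theta, q0$phi, v0a$v)
  out <- deSolve::lsodar(y = y0, times = times, func = geodesic_rhs,
                         parms = list(r_floor = r_floor, pole_eps = pole_eps),
                         rootfunc = geodesic_root,
                         rtol = rtol, atol = atol)
  finish_trajectory(out, q0, v0a, duration,
                    diagnostics = list(steps = attr(out, "istate")[3]))
}

#' @export
print.geodesic_trajectory <- function(x, ...) {
  d <- attr(x, "diagnostics")
  cat(sprintf("<geodesic trajectory>  %d samples over %.3g s%s, metric-speed drift %.2e\n",
              nrow(x), max(x$t),
              if (isTRUE(attr(x, "truncated"))) " (truncated)" else "",
              d$speed_drift))
  NextMethod()
}

as_tangential_dir <- function(e, q0) {
  # bare numerics are Cartesian direction components; tagged vectors are
  # converted from their own basis
  if (!inherits(e, "tangent_vector")) {
    stopifnot(is.numeric(e), length(e) == 3L)
    e <- tangent_vector(e[1], e[2], e[3], "cartesian")
  }
  convert_basis(e, q0, "tangential")$v
}

orthonormal_pair_g <- function(q0, e1, e2) {
  a <- as_tangential_dir(e1, q0)
  b <- as_tangential_dir(e2, q0)
  na <- sqrt(sum(a^2))
  if (na == 0) stop("'e1' must be nonzero.")
  a <- a / na
  b <- b - sum(a * b) * a
  nb <- sqrt(sum(b^2))
  if (nb < 1e-12) stop("'e1' and 'e2' must be linearly independent.")
  b <- b / nb
  list(a = a, b = b)  # Euclidean-unit; multiply by r for unit g-norm
}

#' Family of geodesics from one point in a velocity 2-plane
#'
#' Launches `n_directions` geodesics from `q0` with initial velocities at
#' equal angular spacing in the plane spanned by `e1`, `e2`
#' (orthonormalised). `speed = "metric"` gives unit metric-norm initial
#' velocities; `speed = "euclidean"` gives 1 m/s launches, the physical
#' object speed depicted in the trajectory figures.
#'
#' @param q0 Initial point (any point representation).
#' @param e1,e2 Spanning directions of the initial-velocity plane
#'   ([tangent_vector()]s in any basis; bare numerics are taken as
#'   Cartesian components).
#' @param n_directions Number of equally spaced directions (default 36,
#'   i.e. 10 degree spacing).
#' @param duration,cadence,rtol,atol Passed to [integrate_geodesic()].
#' @param speed `"metric"` or `"euclidean"` initial-speed normalisation.
#' @return A tibble of class `geodesic_family`: the row-bound trajectories
#'   with `traj_id` and `launch_angle` columns.
#' @export
geodesic_family <- function(q0, e1, e2, n_directions = 36, duration = 2,
                            cadence = 0.5, speed = c("metric", "euclidean"),
                            rtol = 1e-11, atol = 1e-13) {
  q0 <- as_cyclopean(q0)
  speed <- match.arg(speed)
  ab <- orthonormal_pair_g(q0, e1, e2)
  scale <- if (speed == "metric") q0$r else 1
  angles <- 2 * pi * (seq_len(n_directions) - 1) / n_directions
  fam <- purrr::map_dfr(seq_along(angles), function(i) {
    v <- scale * (cos(angles[i]) * ab$a + sin(angles[i]) * ab$b)
    tr <- integrate_geodesic(q0, tangent_vector(v[1], v[2], v[3], "tangential"),
                             duration = duration, cadence = cadence,
                             rtol = rtol, atol = atol)
    dplyr::mutate(tibble::as_tibble(tr), traj_id = i, launch_angle = angles[i],
                  .before = 1)
  })
  structure(fam, class = c("geodesic_family", class(fam)),
            q0 = q0, plane = ab, speed = speed)
}

chart_initial_velocity <- function(qA, qB) {
  # Straight-line construction in the (log r) x sphere chart: the exact
  # initial angular velocity of the geodesic reaching qB at t = 1.
  sA <- as.numeric(as_cartesian(qA)) / qA$r
  sB <- as.numeric(as_cartesian(qB)) / qB$r
  du <- log(qB$r / qA$r)
  coss <- min(1, max(-1, sum(sA * sB)))
  sigma <- acos(coss)
  multiplicity <- FALSE
  if (sigma < 1e-12) {
    sdot <- c(0, 0, 0)
  } else {
    tvec <- sB - coss * sA
    nt <- sqrt(sum(tvec^2))
    if (nt < 1e-9) {
      # antipodal on the sphere of directions: great-circle direction is
      # ambiguous; pick one orthogonal to sA and flag it
      multiplicity <- TRUE
      ref <- if (abs(sA[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      tvec <- ref - sum(ref * sA) * sA
      nt <- sqrt(sum(tvec^2))
    }
    sdot <- sigma * tvec / nt
  }
  eth <- c(-sin(qA$theta), cos(qA$theta), 0)
  eph <- c(-sin(qA$phi) * cos(qA$theta), -sin(qA$phi) * sin(qA$theta), cos(qA$phi))
  list(v = c(qA$r * du,
             sum(sdot * eth) / cos(qA$phi),
             sum(sdot * eph)),
       multiplicity = multiplicity)
}

#' Connecting geodesic between two points (shooting method)
#'
#' Finds the geodesic from `qA` to `qB` by shooting over the initial
#' velocity: the terminal Cartesian miss distance at unit time is minimised
#' with a Nelder-Mead search (multi-start with seeded perturbations when
#' needed) followed by a quasi-Newton polish, starting from a chart-based
#' initial guess. Convergence requires an endpoint error below
#' `tol_rel * |qB|`; non-convergence raises an error carrying the best
#' diagnostics. Diametrically opposed points on one visual sphere admit a
#' continuum of connecting great-circle arcs; the first converged solution
#' is returned with a `multiplicity` flag.
#'
#' @param qA,qB Distinct endpoints (any point representation).
#' @param cadence Output sampling of the returned trajectory (in units of
#'   the connecting time, which is normalised to 1 s).
#' @param tol_rel Relative endpoint tolerance.
#' @param n_starts Maximum number of multi-start perturbations.
#' @param seed Seed for the perturbation draws.
#' @param rtol,atol Integrator tolerances.
#' @return A `geodesic_trajectory` with attributes `endpoint_error`,
#'   `converged` and `multiplicity`.
#' @export
two_point_geodesic <- function(qA, qB, cadence = 0.05, tol_rel = 1e-6,
                               n_starts = 8, seed = 1L,
                               rtol = 1e-11, atol = 1e-13) {
  qA <- as_cyclopean(qA); qB <- as_cyclopean(qB)
  xB <- as.numeric(as_cartesian(qB))
  if (sqrt(sum((as.numeric(as_cartesian(qA)) - xB)^2)) < 1e-12) {
    stop("'qA' and 'qB' must be distinct.")
  }
  shoot <- function(v) {
    tr <- integrate_geodesic(qA, tangent_vector(v[1], v[2], v[3], "angular"),
                             duration = 1, cadence = 1,
                             rtol = rtol, atol = atol)
    last <- tr[nrow(tr), ]
    sqrt((last$x - xB[1])^2 + (last$y - xB[2])^2 + (last$z - xB[3])^2)
  }
  tol <- tol_rel * qB$r
  guess <- chart_initial_velocity(qA, qB)
  best_v <- guess$v
  best_err <- shoot(best_v)
  if (best_err > tol) {
    scale <- max(sqrt(sum(guess$v^2)), 1e-3)
    set.seed(seed)
    for (s in seq_len(n_starts)) {
      v0 <- guess$v + if (s == 1) 0 else scale * 0.3 * stats::runif(3, -1, 1)
      opt <- stats::optim(v0, shoot, method = "Nelder-Mead",
                          control = list(maxit = 400, reltol = 1e-14))
      if (opt$value < best_err) { best_err <- opt$value; best_v <- opt$par }
      if (best_err < tol) break
    }
    if (best_err >= tol) {
      opt <- stats::optim(best_v, shoot, method = "BFGS",
                          control = list(maxit = 100, reltol = 1e-14))
      if (opt$value < best_err) { best_err <- opt$value; best_v <- opt$par }
    }
    if (best_err >= tol) {
      stop(sprintf(paste0("two-point geodesic shooting did not converge: ",
                          "best endpoint error %.3g m (tolerance %.3g m)"),
                   best_err, tol))
    }
  }
  tr <- integrate_geodesic(qA, tangent_vector(best_v[1], best_v[2], best_v[3],
                                              "angular"),
                           duration = 1, cadence = cadence,
                           rtol = rtol, atol = atol)
  attr(tr, "endpoint_error") <- best_err
  attr(tr, "converged") <- TRUE
  attr(tr, "multiplicity") <- guess$multiplicity
  tr
}

#' Initial and terminal tangents of a trajectory
#'
#' @param tr A `geodesic_trajectory`.
#' @param end `"initial"` or `"terminal"`.
#' @param basis Output basis.
#' @return A [tangent_vector()] and its base point, as a list `(q, v)`.
#' @export
trajectory_tangent <- function(tr, end = c("initial", "terminal"),
                               basis = "cartesian") {
  end <- match.arg(end)
  row <- if (end == "initial") tr[1, ] else tr[nrow(tr), ]
  q <- cyclopean_point(row$r, row$theta, row$phi)
  v <- tangent_vector(row$dr, row$dtheta, row$dphi, "angular")
  list(q = q, v = convert_basis(v, q, basis))
}
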