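#' Build a sampled curve table
#'
#' Curves on the manifold are carried as tibbles with columns
#' `t, r, theta, phi, dr, dtheta, dphi` (angular coordinates and
#' velocities). When velocities are omitted they are recovered by spline
#' differentiation of the coordinates. [integrate_geodesic()] output is
#' already in this form.
#'
#' @param t Sample times (strictly increasing).
#' @param r,theta,phi Coordinate samples.
#' @param dr,dtheta,dphi Optional velocity samples.
#' @return A curve tibble.
#' @export
curve_tbl <- function(t, r, theta, phi, dr = NULL, dtheta = NULL, dphi = NULL) {
  stopifnot(length(t) >= 3L, all(diff(t) > 0),
            length(r) == length(t), length(theta) == length(t),
            length(phi) == length(t))
  deriv_of <- function(yv) {
    f <- stats::splinefun(t, yv, method = "natural")
    f(t, deriv = 1)
  }
  if (is.null(dr)) dr <- deriv_of(r)
  if (is.null(dtheta)) dtheta <- deriv_of(theta)
  if (is.null(dphi)) dphi <- deriv_of(phi)
  tibble::tibble(t = t, r = r, theta = theta, phi = phi,
                 dr = dr, dtheta = dtheta, dphi = dphi)
}

check_curve <- function(curve) {
  need <- c("t", "r", "theta", "phi", "dr", "dtheta", "dphi")
  if (!all(need %in% names(curve))) {
    stop("a sampled curve needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(curve) < 3L) stop("at least 3 samples are required.")
  curve
}

field_matrix <- function(field, n) {
  m <- if (is.data.frame(field)) {
    as.matrix(field[, intersect(c("g1", "g2", "g3"), names(field))])
  } else {
    as.matrix(field)
  }
  stopifnot(ncol(m) == 3L, nrow(m) == n)
  unname(m)
}

#' Covariant derivative of a vector field along a sampled curve
#'
#' Evaluates `nabla_{alphadot} gamma = gamma' - B(alpha; alphadot, gamma)`
#' at each sample, with `gamma'` by central finite differences in time and
#' the connection term supplied by the symmetric bilinear map of the
#' angular spray ([bilinear_B()]). With `field` equal to the curve's own
#' velocity this is the perceived acceleration `alphaddot - f2`, which
#' vanishes along geodesics and equals minus the spray (the illusory
#' acceleration) along straight uniform Euclidean motion.
#'
#' @param curve A curve tibble (see [curve_tbl()]).
#' @param field `n x 3` matrix (or tibble with `g1, g2, g3`) of angular
#'   components along the curve; defaults to the curve velocity.
#' @return A tibble `t, d1, d2, d3, gnorm` (angular components of the
#'   covariant derivative and its metric norm).
#' @export
covariant_derivative_along <- function(curve, field = NULL) {
  curve <- check_curve(curve)
  n <- nrow(curve)
  if (is.null(field)) field <- cbind(curve$dr, curve$dtheta, curve$dphi)
  gam <- field_matrix(field, n)
  tt <- curve$t
  dgam <- matrix(0, n, 3)
  for (j in 1:3) {
    # central differences on a possibly non-uniform grid; one-sided ends
    dgam[2:(n - 1), j] <- (gam[3:n, j] - gam[1:(n - 2), j]) /
      (tt[3:n] - tt[1:(n - 2)])
    dgam[1, j] <- (gam[2, j] - gam[1, j]) / (tt[2] - tt[1])
    dgam[n, j] <- (gam[n, j] - gam[n - 1, j]) / (tt[n] - tt[n - 1])
  }
  out <- matrix(0, n, 3)
  gn <- numeric(n)
  for (i in seq_len(n)) {
    q <- cyclopean_point(curve$r[i], curve$theta[i], curve$phi[i])
    adot <- c(curve$dr[i], curve$dtheta[i], curve$dphi[i])
    b <- bilinear_B(q, adot, gam[i, ], basis = "angular")$v
    out[i, ] <- dgam[i, ] - b
    gn[i] <- metric_norm(q, tangent_vector(out[i, 1], out[i, 2], out[i, 3],
                                           "angular"))
  }
  tibble::tibble(t = tt, d1 = out[, 1], d2 = out[, 2], d3 = out[, 3],
                 gnorm = gn)
}

#' Parallel transport of a vector along a sampled curve
#'
#' Integrates `gamma' = B(alpha; alphadot, gamma)` (the zero-covariant-
#' derivative condition rearranged) with the curve interpolated by
#' splines. Parallel translation is a linear, invertible isometry, so
#' metric inner products among transported vectors are conserved; the
#' relative drift of `<gamma, gamma>_g` is returned as a diagnostic.
#'
#' @param curve A curve tibble.
#' @param v0 Initial vector at the first sample ([tangent_vector()], any
#'   basis).
#' @param rtol,atol Solver tolerances.
#' @return A tibble `t, g1, g2, g3` of angular components, with attribute
#'   `isometry_drift`.
#' @export
parallel_transport <- function(curve, v0, rtol = 1e-11, atol = 1e-13) {
  curve <- check_curve(curve)
  q0 <- cyclopean_point(curve$r[1], curve$theta[1], curve$phi[1])
  if (!inherits(v0, "tangent_vector")) {
    stopifnot(is.numeric(v0), length(v0) == 3L)
    v0 <- tangent_vector(v0[1], v0[2], v0[3], "angular")
  }
  g0 <- convert_basis(v0, q0, "angular")$v
  sp <- lapply(curve[c("r", "theta", "phi", "dr", "dtheta", "dphi")],
               function(col) stats::splinefun(curve$t, col, method = "natural"))
  rhs <- function(t, y, parms) {
    q <- cyclopean_point(sp$r(t), sp$theta(t), sp$phi(t))
    adot <- c(sp$dr(t), sp$dtheta(t), sp$dphi(t))
    list(bilinear_B(q, adot, y, basis = "angular")$v)
  }
  out <- deSolve::lsoda(y = g0, times = curve$t, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  tb <- tibble::tibble(t = out[, 1], g1 = out[, 2], g2 = out[, 3],
                       g3 = out[, 4])
  norms <- vapply(seq_len(nrow(tb)), function(i) {
    q <- cyclopean_point(curve$r[i], curve$theta[i], curve$phi[i])
    metric_inner(q, tangent_vector(tb$g1[i], tb$g2[i], tb$g3[i], "angular"),
                 tangent_vector(tb$g1[i], tb$g2[i], tb$g3[i], "angular"))
  }, numeric(1))
  attr(tb, "isometry_drift") <- if (norms[1] > 0) {
    max(abs(norms - norms[1])) / norms[1]
  } else 0
  tb
}

#' Metric length of a sampled curve (the perceptual tape measure)
#'
#' Integrates the metric speed `|gammadot|_g` over the sampled interval
#' (composite Simpson on uniform grids, trapezoid otherwise). Because the
#' metric scales as `1/r`, a circular arc about the egocentre has length
#' equal to its subtended angle regardless of radius, and a radial segment
#' from 1 m to R m has length `log(R)`.
#'
#' @param curve A curve tibble.
#' @param t_start,t_end Optional sub-interval limits.
#' @return Metric length (scalar).
#' @export
curve_length <- function(curve, t_start = NULL, t_end = NULL) {
  curve <- check_curve(curve)
  if (!is.null(t_start) || !is.null(t_end)) {
    t_start <- if (is.null(t_start)) min(curve$t) else t_start
    t_end <- if (is.null(t_end)) max(curve$t) else t_end
    curve <- curve[curve$t >= t_start - 1e-12 & curve$t <= t_end + 1e-12, ]
    if (nrow(curve) == 0 || t_end <= t_start) return(0)
  }
  sp <- metric_speed_angular(curve$r, curve$phi, curve$dr, curve$dtheta,
                             curve$dphi)
  tt <- curve$t
  n <- length(tt)
  if (n < 2) return(0)
  h <- diff(tt)
  uniform <- max(abs(h - h[1])) < 1e-9 * max(h)
  if (uniform && n >= 3 && n %% 2 == 1) {
    # composite Simpson
    idx <- seq(1, n - 2, by = 2)
    sum(h[1] / 3 * (sp[idx] + 4 * sp[idx + 1] + sp[idx + 2]))
  } else {
    sum((sp[-1] + sp[-n]) / 2 * h)
  }
}

#' Reparameterise a sampled curve to unit metric speed
#'
#' Computes cumulative metric arc length, inverts it by monotone splines
#' and resamples the curve uniformly in arc length so that its velocity
#' has unit metric norm everywhere.
#'
#' @param curve A curve tibble.
#' @param n Number of output samples.
#' @return A curve tibble with `t` holding arc length `s`.
#' @export
unit_speed_reparameterize <- function(curve, n = nrow(curve)) {
  curve <- check_curve(curve)
  sp <- metric_speed_angular(curve$r, curve$phi, curve$dr, curve$dtheta,
                             curve$dphi)
  if (any(sp <= 0)) stop("curve has zero metric speed; cannot reparameterise.")
  tt <- curve$t
  h <- diff(tt)
  s <- c(0, cumsum((sp[-1] + sp[-length(sp)]) / 2 * h))
  t_of_s <- stats::splinefun(s, tt, method = "hyman")
  s_new <- seq(0, s[length(s)], length.out = n)
  t_new <- t_of_s(s_new)
  f <- lapply(curve[c("r", "theta", "phi")],
              function(col) stats::splinefun(tt, col, method = "natural"))
  curve_tbl(s_new, f$r(t_new), f$theta(t_new), f$phi(t_new))
}

#' Perceived curvature along a boundary curve
#'
#' The perceived curvature of an outline is the metric norm of the
#' covariant acceleration of the unit-metric-speed curve,
#' `kappa(s) = |nabla_{gammadot} gammadot|_g`. Geodesics (radial lines,
#' egocentric circles) have `kappa = 0`; curves that deviate from
#' geodesics pick up positive perceived curvature. Non-unit-speed input is
#' reparameterised automatically with a warning.
#'
#' @param curve A curve tibble.
#' @param tol_speed Accepted relative deviation from unit metric speed.
#' @return A tibble `s, kappa` (endpoints trimmed, where the finite
#'   difference is one-sided).
#' @export
boundary_curvature <- function(curve, tol_speed = 1e-6) {
  curve <- check_curve(curve)
  sp <- metric_speed_angular(curve$r, curve$phi, curve$dr, curve$dtheta,
                             curve$dphi)
  if (max(abs(sp - 1)) > tol_speed) {
    warning("curve is not unit metric speed; reparameterising.")
    curve <- unit_speed_reparameterize(curve, n = max(nrow(curve), 201L))
  }
  cd <- covariant_derivative_along(curve)
  inner <- 2:(nrow(cd) - 1)
  tibble::tibble(s = cd$t[inner], kappa = cd$gnorm[inner])
}
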