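#' Geodesic spray acceleration, angular coordinates
#'
#' The vertical (acceleration) part of the geodesic spray field in the
#' spherical chart: a curve is a geodesic of the perceived metric iff its
#' coordinate acceleration equals this field. Componentwise,
#'
#' `f_r = rdot^2 / r`,
#' `f_theta = 2 tan(phi) thetadot phidot`,
#' `f_phi = -cos(phi) sin(phi) thetadot^2`.
#'
#' The theta component is the form obtained by solving the variational
#' definition of the spray for the angular metric (see
#' [spray_f2_variational()], which reproduces it to round-off). The
#' negative of the spray is the illusory acceleration perceived for an
#' object moving uniformly in a straight line: a point approaching radially
#' at constant speed (`rdot = -1`) carries `f_r = 1/r`, so it appears to
#' accelerate as it nears the observer.
#'
#' @param q A [cyclopean_point()].
#' @param qdot A [tangent_vector()] in the angular basis (or a numeric
#'   length-3 of angular components).
#' @return A [tangent_vector()] (angular basis) holding `f2`.
#' @export
spray_f2_angular <- function(q, qdot) {
  stopifnot(inherits(q, "cyclopean_point"))
  v <- spray_components(qdot, "angular")
  f <- spray_f2_angular_raw(q$r, q$phi, v)
  tangent_vector(f[1], f[2], f[3], "angular")
}

spray_components <- function(v, basis) {
  if (inherits(v, "tangent_vector")) {
    if (v$basis != basis) {
      stop("spray evaluated in the ", basis,
           " basis requires a ", basis, "-basis velocity; convert explicitly.")
    }
    v$v
  } else {
    stopifnot(is.numeric(v), length(v) == 3L)
    as.numeric(v)
  }
}

spray_f2_angular_raw <- function(r, phi, v) {
  c(v[1]^2 / r,
    2 * tan(phi) * v[2] * v[3],
    -cos(phi) * sin(phi) * v[2]^2)
}

#' Geodesic spray acceleration, tangential-velocity components
#'
#' The spray field is non-tensorial, so re-expressing it in the tangential
#' (physical-velocity) components gives a different formula:
#'
#' `f_r = (v_r^2 - v_theta^2 - v_phi^2) / r`,
#' `f_theta = 2 v_r v_theta / r`,
#' `f_phi = 2 v_r v_phi / r`.
#'
#' For `v = (0, 1, 0)` this is the centripetal acceleration `-1/r` of
#' constant-tangential-speed circular motion about the egocentre; for
#' `v = (1, 1, 0)` the radial parts cancel and a Coriolis-like tangential
#' acceleration `2 v_r v_theta / r` remains.
#'
#' @param q A [cyclopean_point()].
#' @param v A [tangent_vector()] in the tangential basis (or numeric
#'   length 3).
#' @return A [tangent_vector()] (tangential basis) holding `f2`.
#' @export
spray_f2_tangential <- function(q, v) {
  stopifnot(inherits(q, "cyclopean_point"))
  vv <- spray_components(v, "tangential")
  r <- q$r
  f <- c((vv[1]^2 - vv[2]^2 - vv[3]^2) / r,
         2 * vv[1] * vv[2] / r,
         2 * vv[1] * vv[3] / r)
  tangent_vector(f[1], f[2], f[3], "tangential")
}

#' Spray acceleration from the variational definition
#'
#' Solves, for `f2`, the identity
#' `<g f2, w> = (1/2) <g'_w qdot, qdot> - <g'_qdot qdot, w>` over the three
#' coordinate directions `w`, where `g'_u` is the directional derivative of
#' the metric matrix along `u` (central differences). This is the defining
#' property of the spray and serves as an independent check of the closed
#' forms in [spray_f2_angular()] and [spray_f2_tangential()].
#'
#' @param q A [cyclopean_point()].
#' @param qdot Velocity components (numeric length 3 or [tangent_vector()])
#'   in the chosen basis.
#' @param basis `"angular"` or `"tangential"`.
#' @param h Finite-difference step.
#' @return A [tangent_vector()] in the chosen basis.
#' @export
spray_f2_variational <- function(q, qdot, basis = c("angular", "tangential"),
                                 h = NULL) {
  stopifnot(inherits(q, "cyclopean_point"))
  basis <- match.arg(basis)
  if (is.null(h)) h <- 1e-5 * max(q$r, 1)
  v <- spray_components(qdot, basis)
  gfun <- metric_coord_fn(basis)
  x <- c(q$r, q$theta, q$phi)
  g0 <- gfun(x)
  dmetric <- function(u) {
    # directional derivative of the metric matrix along coordinate direction u
    nu <- sqrt(sum(u^2))
    if (nu == 0) return(matrix(0, 3, 3))
    (gfun(x + h * u / nu) - gfun(x - h * u / nu)) / (2 * h) * nu
  }
  gv <- dmetric(v)
  rhs <- numeric(3)
  for (i in 1:3) {
    w <- c(0, 0, 0); w[i] <- 1
    gw <- dmetric(w)
    rhs[i] <- 0.5 * as.numeric(v %*% gw %*% v) - as.numeric(v %*% gv %*% w)
  }
  f2 <- solve(g0, rhs)
  tangent_vector(f2[1], f2[2], f2[3], basis)
}

#' Symmetric bilinear map associated with the spray
#'
#' `B(q; u, w) = (1/2) [f2(q, u + w) - f2(q, u) - f2(q, w)]`, the
#' polarisation of the quadratic spray, satisfying `B(q; v, v) = f2(q, v)`.
#' Its negative contracted with the Christoffel symbols,
#' `B^i = -G^i_jk u^j w^k`, supplies the connection term of covariant
#' derivatives along curves.
#'
#' @param q A [cyclopean_point()].
#' @param u,w [tangent_vector()]s in a common basis (`"angular"` or
#'   `"tangential"`), or numeric length-3 vectors with `basis` given.
#' @param basis Basis of `u` and `w` when they are bare numerics.
#' @return A [tangent_vector()] in the same basis.
#' @export
bilinear_B <- function(q, u, w, basis = NULL) {
  if (inherits(u, "tangent_vector")) basis <- u$basis
  if (is.null(basis)) stop("supply tangent vectors or an explicit basis.")
  if (inherits(w, "tangent_vector") && w$basis != basis) {
    stop("'u' and 'w' must share a basis; convert explicitly.")
  }
  uu <- spray_components(u, basis)
  ww <- spray_components(w, basis)
  f2 <- switch(basis,
    angular    = function(z) spray_f2_angular(q, z)$v,
    tangential = function(z) spray_f2_tangential(q, z)$v,
    stop("bilinear_B is defined for the angular and tangential bases.")
  )
  b <- (f2(uu + ww) - f2(uu) - f2(ww)) / 2
  tangent_vector(b[1], b[2], b[3], basis)
}
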