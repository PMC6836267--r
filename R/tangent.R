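#' Tangent vector with an explicit basis tag
#'
#' Velocities and directions on the perceived visual manifold are carried in
#' one of three bases, and mixing bases without explicit conversion is an
#' error:
#'
#' * `"angular"` — coordinate velocities `(rdot, thetadot, phidot)` of the
#'   spherical chart;
#' * `"tangential"` — physical velocities `(v_r, v_theta, v_phi)` along the
#'   orthonormal radial/azimuthal/elevational frame, related to the angular
#'   components by `v_r = rdot`, `v_theta = r cos(phi) thetadot`,
#'   `v_phi = r phidot`;
#' * `"cartesian"` — `(xdot, ydot, zdot)`.
#'
#' @param c1,c2,c3 Components.
#' @param basis One of `"angular"`, `"tangential"`, `"cartesian"`.
#' @return An object of class `tangent_vector`.
#' @export
tangent_vector <- function(c1, c2, c3, basis = c("angular", "tangential", "cartesian")) {
  basis <- match.arg(basis)
  v <- c(c1, c2, c3)
  stopifnot(is.numeric(v), length(v) == 3L, all(is.finite(v)))
  structure(list(v = as.numeric(v), basis = basis), class = "tangent_vector")
}

#' @export
print.tangent_vector <- function(x, ...) {
  cat(sprintf("<tangent vector, %s basis>  (%.6g, %.6g, %.6g)\n",
              x$basis, x$v[1], x$v[2], x$v[3]))
  invisible(x)
}

# Orthonormal frame (e_r, e_theta, e_phi) at q, columns in Cartesian coords.
frame_at <- function(q) {
  ct <- cos(q$theta); st <- sin(q$theta)
  cp <- cos(q$phi);   sp <- sin(q$phi)
  cbind(e_r     = c(cp * ct, cp * st, sp),
        e_theta = c(-st, ct, 0),
        e_phi   = c(-sp * ct, -sp * st, cp))
}

#' Convert a tangent vector between bases at a point
#'
#' All conversions are exact linear maps at the point `q`; forward and
#' inverse maps compose to the identity. The angular/tangential conversion
#' divides by `cos(phi)` and is therefore rejected at the poles (already
#' excluded by [cyclopean_point()]).
#'
#' @param v A [tangent_vector()].
#' @param q The base point, a [cyclopean_point()].
#' @param to Target basis.
#' @return A [tangent_vector()] in the target basis.
#' @export
#' @examples
#' q <- cyclopean_point(2, 0, 0)
#' convert_basis(tangent_vector(0, 1, 0, "angular"), q, "tangential")
convert_basis <- function(v, q, to = c("angular", "tangential", "cartesian")) {
  stopifnot(inherits(v, "tangent_vector"), inherits(q, "cyclopean_point"))
  to <- match.arg(to)
  if (v$basis == to) return(v)
  tang <- switch(v$basis,
    tangential = v$v,
    angular = c(v$v[1], q$r * cos(q$phi) * v$v[2], q$r * v$v[3]),
    cartesian = as.numeric(crossprod(frame_at(q), v$v))
  )
  out <- switch(to,
    tangential = tang,
    angular = c(tang[1], tang[2] / (q$r * cos(q$phi)), tang[3] / q$r),
    cartesian = as.numeric(frame_at(q) %*% tang)
  )
  tangent_vector(out[1], out[2], out[3], to)
}

#' @rdname convert_basis
#' @export
angular_to_tangential <- function(q, v) {
  stopifnot(identical(v$basis, "angular"))
  convert_basis(v, q, "tangential")
}

#' @rdname convert_basis
#' @export
tangential_to_angular <- function(q, v) {
  stopifnot(identical(v$basis, "tangential"))
  convert_basis(v, q, "angular")
}
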