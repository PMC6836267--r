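#' Cyclopean point
#'
#' A point of the perceived visual manifold, given in cyclopean spherical
#' coordinates measured from the egocentre: `r` the Euclidean cyclopean
#' distance in metres, `theta` the azimuth in radians measured
#' counterclockwise from the +x axis in the horizontal plane, and `phi` the
#' elevation in radians above the horizontal plane.
#'
#' `r` must be strictly positive and `phi` strictly inside
#' `(-pi/2, pi/2)`: at the poles the angular metric degenerates and the
#' tangential/angular basis conversion divides by `cos(phi)`. The exclusion
#' band at the poles is `pole_eps` (default `1e-6` rad).
#'
#' Distances below 1 m are allowed; the perceived (logarithmic) distance is
#' then simply negative. See [perceived_distance()].
#'
#' @param r Euclidean cyclopean distance, metres (> 0).
#' @param theta Azimuth, radians.
#' @param phi Elevation, radians, inside `(-pi/2, pi/2)`.
#' @param pole_eps Half-width of the excluded band about the poles.
#' @return An object of class `cyclopean_point`.
#' @seealso [cartesian_point()], [spherical_to_cartesian()]
#' @export
#' @examples
#' q <- cyclopean_point(5, pi / 2, 0)
#' spherical_to_cartesian(q)
cyclopean_point <- function(r, theta, phi = 0, pole_eps = 1e-6) {
  stopifnot(is.numeric(r), is.numeric(theta), is.numeric(phi),
            length(r) == 1L, length(theta) == 1L, length(phi) == 1L,
            is.finite(r), is.finite(theta), is.finite(phi))
  if (r <= 0) {
    stop("'r' must be strictly positive (the egocentric origin is excluded).")
  }
  if (abs(phi) >= pi / 2 - pole_eps) {
    stop("'phi' must lie strictly inside (-pi/2, pi/2): the metric ",
         "degenerates at the poles.")
  }
  structure(list(r = r, theta = theta, phi = phi),
            class = "cyclopean_point")
}

#' @export
print.cyclopean_point <- function(x, ...) {
  cat(sprintf("<cyclopean point>  r = %.6g m, theta = %.6g rad, phi = %.6g rad\n",
              x$r, x$theta, x$phi))
  invisible(x)
}

#' @export
format.cyclopean_point <- function(x, ...) {
  sprintf("(r=%.4g, theta=%.4g, phi=%.4g)", x$r, x$theta, x$phi)
}

#' Cartesian point
#'
#' A point of the outside world in egocentric Cartesian coordinates (metres).
#' The egocentre is the origin; +x is the azimuth reference direction, +z is
#' up.
#'
#' @param x,y,z Coordinates in metres.
#' @return An object of class `cartesian_point` (a named numeric of length 3).
#' @export
cartesian_point <- function(x, y, z = 0) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(z),
            all(is.finite(c(x, y, z))))
  structure(c(x = x, y = y, z = z), class = "cartesian_point")
}

#' @export
print.cartesian_point <- function(x, ...) {
  cat(sprintf("<cartesian point>  (%.6g, %.6g, %.6g) m\n", x[1], x[2], x[3]))
  invisible(x)
}

#' Convert cyclopean spherical coordinates to Cartesian coordinates
#'
#' Uses the convention `x = r cos(phi) cos(theta)`,
#' `y = r cos(phi) sin(theta)`, `z = r sin(phi)`.
#'
#' @param q A [cyclopean_point()].
#' @return A [cartesian_point()].
#' @export
spherical_to_cartesian <- function(q) {
  stopifnot(inherits(q, "cyclopean_point"))
  cartesian_point(q$r * cos(q$phi) * cos(q$theta),
                  q$r * cos(q$phi) * sin(q$theta),
                  q$r * sin(q$phi))
}

#' Convert Cartesian coordinates to cyclopean spherical coordinates
#'
#' Inverse of [spherical_to_cartesian()] with ranges `theta` in `(-pi, pi]`
#' and `phi` in `(-pi/2, pi/2)`. The origin is rejected (`r = 0` has no
#' direction) and so are points within the polar exclusion band.
#'
#' @param p A [cartesian_point()] or numeric vector of length 3.
#' @param pole_eps Passed to [cyclopean_point()].
#' @return A [cyclopean_point()].
#' @export
cartesian_to_spherical <- function(p, pole_eps = 1e-6) {
  p <- as.numeric(p)
  stopifnot(length(p) == 3L, all(is.finite(p)))
  r <- sqrt(sum(p^2))
  if (r == 0) stop("the egocentric origin has undefined direction (r = 0).")
  cyclopean_point(r, atan2(p[2], p[1]), asin(p[3] / r), pole_eps = pole_eps)
}

#' @rdname spherical_to_cartesian
#' @export
as_cartesian <- function(q) {
  if (inherits(q, "cartesian_point")) return(q)
  if (is.numeric(q) && length(q) == 3L) return(cartesian_point(q[1], q[2], q[3]))
  spherical_to_cartesian(q)
}

#' @rdname cartesian_to_spherical
#' @export
as_cyclopean <- function(p, pole_eps = 1e-6) {
  if (inherits(p, "cyclopean_point")) return(p)
  cartesian_to_spherical(p, pole_eps = pole_eps)
}

#' @export
as.data.frame.cyclopean_point <- function(x, ...) {
  data.frame(r = x$r, theta = x$theta, phi = x$phi)
}

#' Serialize points and tangent vectors to a tibble
#'
#' Column order is `r, theta, phi, basis, c1, c2, c3`; when no vector is
#' supplied the component columns are `NA`. This is the documented CSV/JSON
#' column convention used by the command-line tools.
#'
#' @param q A [cyclopean_point()].
#' @param v Optionally a [tangent_vector()].
#' @return A one-row tibble.
#' @export
point_record <- function(q, v = NULL) {
  stopifnot(inherits(q, "cyclopean_point"))
  if (is.null(v)) {
    tibble::tibble(r = q$r, theta = q$theta, phi = q$phi,
                   basis = NA_character_,
                   c1 = NA_real_, c2 = NA_real_, c3 = NA_real_)
  } else {
    stopifnot(inherits(v, "tangent_vector"))
    tibble::tibble(r = q$r, theta = q$theta, phi = q$phi,
                   basis = v$basis, c1 = v$v[1], c2 = v$v[2], c3 = v$v[3])
  }
}
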