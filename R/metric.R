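#' Metric tensor of the perceived visual manifold
#'
#' The perceived metric is the Euclidean metric scaled conformally by
#' `1/r^2`, where `r` is the Euclidean cyclopean distance. Its matrix
#' depends on the basis:
#'
#' * angular basis: `diag(1/r^2, cos(phi)^2, 1)`;
#' * tangential basis: `(1/r^2) * I`;
#' * Cartesian basis: `(1/(x^2+y^2+z^2)) * I`.
#'
#' @param q A [cyclopean_point()].
#' @param basis Basis in which the matrix is expressed.
#' @return An object of class `metric_tensor`: a list with the symmetric
#'   positive-definite 3x3 matrix `m`, the `basis` tag and the `point`.
#' @seealso [euclidean_metric_matrix()] for the unscaled Euclidean metric.
#' @export
#' @examples
#' metric_matrix(cyclopean_point(2, 0, 0), "tangential")$m  # 0.25 * I
metric_matrix <- function(q, basis = c("angular", "tangential", "cartesian")) {
  stopifnot(inherits(q, "cyclopean_point"))
  basis <- match.arg(basis)
  m <- switch(basis,
    angular    = diag(c(1 / q$r^2, cos(q$phi)^2, 1)),
    tangential = diag(3) / q$r^2,
    cartesian  = diag(3) / q$r^2
  )
  structure(list(m = m, basis = basis, point = q), class = "metric_tensor")
}

#' Euclidean metric in the three bases
#'
#' The flat metric of the outside world: `diag(1, r^2 cos(phi)^2, r^2)` in
#' the angular basis and the identity in the tangential and Cartesian bases.
#' At every point and in every basis the perceived metric equals
#' `(1/r^2)` times this matrix.
#'
#' @inheritParams metric_matrix
#' @return A `metric_tensor`.
#' @export
euclidean_metric_matrix <- function(q, basis = c("angular", "tangential", "cartesian")) {
  stopifnot(inherits(q, "cyclopean_point"))
  basis <- match.arg(basis)
  m <- switch(basis,
    angular    = diag(c(1, q$r^2 * cos(q$phi)^2, q$r^2)),
    tangential = diag(3),
    cartesian  = diag(3)
  )
  structure(list(m = m, basis = basis, point = q), class = "metric_tensor")
}

#' @export
print.metric_tensor <- function(x, ...) {
  cat(sprintf("<metric tensor, %s basis at %s>\n", x$basis,
              format(x$point)))
  print(x$m)
  invisible(x)
}

metric_of <- function(q, basis, euclidean = FALSE) {
  if (euclidean) euclidean_metric_matrix(q, basis)$m else metric_matrix(q, basis)$m
}

common_basis <- function(q, v, w) {
  if (v$basis != w$basis) w <- convert_basis(w, q, v$basis)
  list(v = v, w = w, basis = v$basis)
}

#' Metric inner product, norm and angle
#'
#' `metric_inner` evaluates the perceived (conformal) inner product of two
#' tangent vectors at `q`; vectors in different bases are converted to a
#' common basis first. `metric_norm` is the induced norm, and `metric_angle`
#' the angle `acos(<v,w> / (|v||w|))` in `[0, pi]`. Because the metric is
#' conformal to the Euclidean one, metric angles equal Euclidean angles,
#' while metric norms are `1/r` times Euclidean norms.
#'
#' @param q A [cyclopean_point()].
#' @param v,w [tangent_vector()]s.
#' @param euclidean If `TRUE` use the flat outside-world metric instead.
#' @return A scalar.
#' @export
metric_inner <- function(q, v, w, euclidean = FALSE) {
  cb <- common_basis(q, v, w)
  g <- metric_of(q, cb$basis, euclidean)
  as.numeric(cb$v$v %*% g %*% cb$w$v)
}

#' @rdname metric_inner
#' @export
metric_norm <- function(q, v, euclidean = FALSE) {
  sqrt(max(metric_inner(q, v, v, euclidean), 0))
}

#' @rdname metric_inner
#' @export
metric_angle <- function(q, v, w, euclidean = FALSE) {
  nv <- metric_norm(q, v, euclidean)
  nw <- metric_norm(q, w, euclidean)
  if (nv == 0 || nw == 0) {
    stop("angle with a zero-length vector is undefined.")
  }
  cosx <- metric_inner(q, v, w, euclidean) / (nv * nw)
  acos(min(1, max(-1, cosx)))
}

#' Perceived (logarithmic) distance along the line of gaze
#'
#' The perceived distance of a point at Euclidean cyclopean distance
#' `r_euclid` is the metric length of the radial segment from the unit
#' sphere to the point, `integral of (1/r) dr from 1 to r_euclid`, i.e.
#' `log(r_euclid)`. It is negative inside 1 m (the perceptual "hole" about
#' the egocentre is documented, not enforced). `method = "quadrature"`
#' evaluates the defining integral numerically instead of using the closed
#' form; the two agree to much better than `1e-8`.
#'
#' @param r_euclid Euclidean distance in metres, > 0 (vectorised).
#' @param method `"closed"` (the logarithm) or `"quadrature"`.
#' @return Perceived distance (dimensionless metric length).
#' @seealso [perceived_distance_inverse()]
#' @export
#' @examples
#' perceived_distance(c(1, exp(1), 10))
perceived_distance <- function(r_euclid, method = c("closed", "quadrature")) {
  method <- match.arg(method)
  stopifnot(is.numeric(r_euclid), all(is.finite(r_euclid)))
  if (any(r_euclid <= 0)) stop("'r_euclid' must be strictly positive.")
  if (method == "closed") return(log(r_euclid))
  vapply(r_euclid, function(rr) {
    if (rr == 1) return(0)
    sgn <- if (rr >= 1) 1 else -1
    lo <- min(1, rr); hi <- max(1, rr)
    sgn * stats::integrate(function(s) 1 / s, lo, hi,
                           rel.tol = 1e-12, abs.tol = 1e-12)$value
  }, numeric(1))
}

#' @rdname perceived_distance
#' @param r_perceived Perceived distance (any real number).
#' @export
perceived_distance_inverse <- function(r_perceived) {
  stopifnot(is.numeric(r_perceived), all(is.finite(r_perceived)))
  exp(r_perceived)
}
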