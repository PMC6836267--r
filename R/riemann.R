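#' Riemann curvature tensor arrays
#'
#' Builds the 3x3x3x3 curvature component arrays at a point from the
#' Christoffel symbols,
#' `R_ijk^l = d_i G^l_jk - d_j G^l_ki + G^m_jk G^l_mi - G^m_ki G^l_mj`,
#' with the partial derivatives taken analytically, and lowers the last
#' index with the metric (`R_ijkl = g_lm R_ijk^m`).
#'
#' In the default tangential frame (the frame of
#' [christoffel_closed_form()], in which the metric matrix is `(1/r^2) I`
#' depending on the first component only) the symmetry-distinct nonzero
#' lowered components are exactly `R_1221 = R_1331 = R_2332 = -1/r^4`.
#' In the `"angular"` basis the arrays are those of the spherical-chart
#' coordinate metric `diag(1/r^2, cos(phi)^2, 1)`, whose curvature is
#' carried entirely by the visual-sphere plane — the form used by the
#' embedded-surface machinery, for which the Gauss relation holds (see
#' [shape_operator()]). The methods vignette discusses how the two
#' computations differ and why.
#'
#' @param q A [cyclopean_point()].
#' @param basis `"tangential"` (default) or `"angular"`.
#' @param euclidean If `TRUE`, curvature of the flat outside-world metric
#'   (identically zero up to the representation).
#' @return An object of class `curvature_array`: list with `up` and `down`
#'   3x3x3x3 arrays, the `basis` tag and the `point`.
#' @export
#' @examples
#' riemann_tensor(cyclopean_point(1, 0, 0))$down[1, 2, 2, 1]  # -1
riemann_tensor <- function(q, basis = c("tangential", "angular"),
                           euclidean = FALSE) {
  stopifnot(inherits(q, "cyclopean_point"))
  basis <- match.arg(basis)
  ch <- if (basis == "tangential") {
    if (euclidean) {
      structure(list(gamma = array(0, c(3, 3, 3)), basis = basis, point = q),
                class = "christoffel_array")
    } else {
      christoffel_closed_form(q)
    }
  } else {
    christoffel_angular(q, euclidean = euclidean)
  }
  dg <- christoffel_derivatives(q, basis, euclidean)
  riemann_from_gamma(ch$gamma, dg,
                     metric_of(q, basis, euclidean = euclidean),
                     q, basis)
}

# Analytic coordinate derivatives dgamma[i, j, k, d] = d G^i_jk / d x_d.
christoffel_derivatives <- function(q, basis, euclidean = FALSE) {
  r <- q$r; phi <- q$phi
  dg <- array(0, c(3, 3, 3, 3))
  sec2 <- 1 / cos(phi)^2
  cos2phi <- cos(phi)^2 - sin(phi)^2
  if (basis == "tangential") {
    if (!euclidean) {
      # all nonzero symbols are c/r, so d/dr = -G/r
      dg[, , , 1] <- -christoffel_closed_form(q)$gamma / r
    }
  } else if (!euclidean) {
    dg[1, 1, 1, 1] <- 1 / r^2
    dg[2, 2, 3, 3] <- dg[2, 3, 2, 3] <- -sec2
    dg[3, 2, 2, 3] <- cos2phi
  } else {
    dg[1, 2, 2, 1] <- -cos(phi)^2
    dg[1, 2, 2, 3] <- 2 * r * cos(phi) * sin(phi)
    dg[1, 3, 3, 1] <- -1
    dg[2, 1, 2, 1] <- dg[2, 2, 1, 1] <- -1 / r^2
    dg[2, 2, 3, 3] <- dg[2, 3, 2, 3] <- -sec2
    dg[3, 1, 3, 1] <- dg[3, 3, 1, 1] <- -1 / r^2
    dg[3, 2, 2, 3] <- cos2phi
  }
  dg
}

# Assemble up/down arrays from gamma and its coordinate derivatives.
riemann_from_gamma <- function(gamma, dgamma, g, q, basis) {
  up <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    s <- dgamma[l, j, k, i] - dgamma[l, k, i, j]
    for (m in 1:3) {
      s <- s + gamma[m, j, k] * gamma[l, m, i] - gamma[m, k, i] * gamma[l, m, j]
    }
    up[i, j, k, l] <- s
  }
  down <- array(0, c(3, 3, 3, 3))
  for (l in 1:3) for (m in 1:3) {
    if (g[l, m] != 0) down[, , , l] <- down[, , , l] + g[l, m] * up[, , , m]
  }
  structure(list(up = up, down = down, basis = basis, point = q),
            class = "curvature_array")
}

#' @export
print.curvature_array <- function(x, ...) {
  nz <- which(abs(x$down) * x$point$r^4 > 1e-9, arr.ind = TRUE)
  cat(sprintf("<curvature array, %s basis at %s>  %d nonzero lowered components\n",
              x$basis, format(x$point), nrow(nz)))
  invisible(x)
}

#' Full curvature contraction Rm(a, b, c, d)
#'
#' Contracts the lowered curvature array with four component vectors.
#'
#' @param cv A `curvature_array`.
#' @param a,b,cc,d Numeric component vectors (length 3) in `cv`'s basis.
#' @return Scalar.
#' @export
riemann_contract <- function(cv, a, b, cc, d) {
  stopifnot(inherits(cv, "curvature_array"))
  s <- 0
  down <- cv$down
  for (i in 1:3) {
    if (a[i] == 0) next
    for (j in 1:3) {
      if (b[j] == 0) next
      for (k in 1:3) {
        if (cc[k] == 0) next
        for (l in 1:3) {
          s <- s + down[i, j, k, l] * a[i] * b[j] * cc[k] * d[l]
        }
      }
    }
  }
  s
}

components_in <- function(v, q, basis) {
  if (inherits(v, "tangent_vector")) convert_basis(v, q, basis)$v else {
    stopifnot(is.numeric(v), length(v) == 3L)
    as.numeric(v)
  }
}

#' Sectional curvature components of the perceived manifold
#'
#' `K(e1, e2) = Rm(e1, e2, e2, e1)` evaluated on the plane spanned by `e1`
#' and `e2` in the tangential frame, after Gram-Schmidt orthogonalisation
#' and scaling to unit Euclidean length. With this normalisation the
#' coordinate planes return the printed component values `-1/r^4`
#' (curvature per unit Euclidean area of the section); the r-sweep identity
#' `K * r^4 = -1` holds at every radius. The value depends only on the
#' plane, not on the particular spanning pair.
#'
#' For the normalised sectional curvature of the spherical-chart coordinate
#' metric — the quantity entering the Gauss relation for embedded surfaces —
#' see [ambient_sectional_curvature()].
#'
#' @param q A [cyclopean_point()].
#' @param e1,e2 Linearly independent [tangent_vector()]s (or numeric
#'   tangential components).
#' @return Scalar curvature component.
#' @export
#' @examples
#' sectional_curvature(cyclopean_point(1, 0, 0),
#'                     tangent_vector(1, 0, 0, "tangential"),
#'                     tangent_vector(0, 1, 0, "tangential"))  # -1
sectional_curvature <- function(q, e1, e2) {
  stopifnot(inherits(q, "cyclopean_point"))
  a <- components_in(e1, q, "tangential")
  b <- components_in(e2, q, "tangential")
  # Gram-Schmidt in the Euclidean sense; unit Euclidean length
  na <- sqrt(sum(a^2))
  if (na == 0) stop("'e1' must be nonzero.")
  a <- a / na
  b <- b - sum(a * b) * a
  nb <- sqrt(sum(b^2))
  if (nb < 1e-12) stop("'e1' and 'e2' are parallel; a 2-plane is required.")
  b <- b / nb
  cv <- riemann_tensor(q, "tangential")
  riemann_contract(cv, a, b, b, a)
}

#' Normalised ambient sectional curvature (spherical-chart metric)
#'
#' The sectional curvature of the perceived metric in its spherical
#' coordinate chart, normalised by the metric area of the spanning pair:
#' `K = Rm(e1, e2, e2, e1) / (|e1|^2 |e2|^2 - <e1, e2>^2)` (all metric
#' quantities). This is the curvature entering the Gauss relation
#' `kappa1 kappa2 = K_induced - K_ambient` for embedded surfaces. It
#' vanishes on planes containing the radial direction and is carried by the
#' visual-sphere planes.
#'
#' @param q A [cyclopean_point()].
#' @param e1,e2 Independent [tangent_vector()]s (or angular components).
#' @param euclidean If `TRUE`, use the flat ambient metric (returns ~0).
#' @return Scalar.
#' @export
ambient_sectional_curvature <- function(q, e1, e2, euclidean = FALSE) {
  stopifnot(inherits(q, "cyclopean_point"))
  a <- components_in(e1, q, "angular")
  b <- components_in(e2, q, "angular")
  g <- metric_of(q, "angular", euclidean = euclidean)
  gaa <- as.numeric(a %*% g %*% a)
  gbb <- as.numeric(b %*% g %*% b)
  gab <- as.numeric(a %*% g %*% b)
  area2 <- gaa * gbb - gab^2
  if (area2 < 1e-14 * gaa * gbb) {
    stop("'e1' and 'e2' are (numerically) parallel.")
  }
  cv <- riemann_tensor(q, "angular", euclidean = euclidean)
  riemann_contract(cv, a, b, b, a) / area2
}
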