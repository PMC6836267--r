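#' Embedded surface patch r = f(theta, phi)
#'
#' A smooth 2D surface embedded in the perceived visual manifold, described
#' by the cyclopean distance as a function of gaze direction over a
#' rectangular parameter domain (poles excluded, `f > 0`). First and second
#' parameter derivatives may be supplied analytically; otherwise they are
#' evaluated by central finite differences.
#'
#' @param f Function `(theta, phi) -> r`.
#' @param derivs Optional named list of functions `f_theta, f_phi,
#'   f_thetatheta, f_thetaphi, f_phiphi`.
#' @param domain Numeric `c(theta_min, theta_max, phi_min, phi_max)`.
#' @param fd_step Finite-difference step for missing derivatives.
#' @return An object of class `surface_patch`.
#' @seealso [patch_sphere()], [patch_plane_z()], [patch_cylinder()],
#'   [patch_bump()], [patch_offset_sphere()]
#' @export
surface_patch <- function(f, derivs = list(),
                          domain = c(-pi / 2, pi / 2, -1, 1),
                          fd_step = 1e-5) {
  stopifnot(is.function(f), length(domain) == 4L)
  d <- list(
    f_theta = derivs$f_theta %||%
      function(th, ph) (f(th + fd_step, ph) - f(th - fd_step, ph)) / (2 * fd_step),
    f_phi = derivs$f_phi %||%
      function(th, ph) (f(th, ph + fd_step) - f(th, ph - fd_step)) / (2 * fd_step),
    f_thetatheta = derivs$f_thetatheta %||%
      function(th, ph) (f(th + fd_step, ph) - 2 * f(th, ph) +
                          f(th - fd_step, ph)) / fd_step^2,
    f_phiphi = derivs$f_phiphi %||%
      function(th, ph) (f(th, ph + fd_step) - 2 * f(th, ph) +
                          f(th, ph - fd_step)) / fd_step^2,
    f_thetaphi = derivs$f_thetaphi %||%
      function(th, ph) (f(th + fd_step, ph + fd_step) -
                          f(th + fd_step, ph - fd_step) -
                          f(th - fd_step, ph + fd_step) +
                          f(th - fd_step, ph - fd_step)) / (4 * fd_step^2)
  )
  structure(list(f = f, d = d, domain = domain), class = "surface_patch")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.surface_patch <- function(x, ...) {
  cat(sprintf("<surface patch>  theta in [%.3g, %.3g], phi in [%.3g, %.3g]\n",
              x$domain[1], x$domain[2], x$domain[3], x$domain[4]))
  invisible(x)
}

#' Built-in analytic surface patches
#'
#' * `patch_sphere(r0)` — visual sphere `r = r0` (totally geodesic in the
#'   perceived manifold; perceived as a frontal plane).
#' * `patch_plane_z(c)` — Euclidean horizontal plane `z = c`
#'   (`r = c / sin(phi)`).
#' * `patch_cylinder(a)` — Euclidean circular cylinder about the vertical
#'   axis, radius `a` (`r = a / cos(phi)`).
#' * `patch_bump(...)` — Gaussian bump on a visual sphere,
#'   `r = r0 + amp * exp(-((theta-th0)^2 + (phi-ph0)^2) / w^2)`.
#' * `patch_offset_sphere(rho, c)` — Euclidean sphere of radius `rho`
#'   centred at `(0, c, 0)` (near sheet; requires `rho < c`), the convex
#'   test object for the flattening analysis.
#'
#' @param r0,a,c,rho,amp,th0,ph0,w Shape parameters (metres, radians).
#' @param domain Parameter domain passed to [surface_patch()].
#' @return A `surface_patch`.
#' @name builtin_patches
NULL

#' @rdname builtin_patches
#' @export
patch_sphere <- function(r0, domain = c(-pi, pi, -1.2, 1.2)) {
  zero <- function(th, ph) 0 * th * ph
  surface_patch(function(th, ph) r0 + 0 * th * ph,
                derivs = list(f_theta = zero, f_phi = zero,
                              f_thetatheta = zero, f_phiphi = zero,
                              f_thetaphi = zero),
                domain = domain)
}

#' @rdname builtin_patches
#' @export
patch_plane_z <- function(c = 1, domain = c(-pi, pi, 0.3, 1.3)) {
  surface_patch(
    function(th, ph) c / sin(ph),
    derivs = list(
      f_theta = function(th, ph) 0 * th,
      f_phi = function(th, ph) -c * cos(ph) / sin(ph)^2,
      f_thetatheta = function(th, ph) 0 * th,
      f_thetaphi = function(th, ph) 0 * th,
      f_phiphi = function(th, ph) c * (1 / sin(ph) + 2 * cos(ph)^2 / sin(ph)^3)
    ),
    domain = domain)
}

#' @rdname builtin_patches
#' @export
patch_cylinder <- function(a = 1, domain = c(-pi, pi, -0.6, 0.6)) {
  surface_patch(
    function(th, ph) a / cos(ph),
    derivs = list(
      f_theta = function(th, ph) 0 * th,
      f_phi = function(th, ph) a * sin(ph) / cos(ph)^2,
      f_thetatheta = function(th, ph) 0 * th,
      f_thetaphi = function(th, ph) 0 * th,
      f_phiphi = function(th, ph) a * (1 + sin(ph)^2) / cos(ph)^3
    ),
    domain = domain)
}

#' @rdname builtin_patches
#' @export
patch_bump <- function(r0 = 2, amp = 0.3, th0 = 0, ph0 = 0, w = 0.5,
                       domain = c(-1, 1, -1, 1)) {
  e <- function(th, ph) exp(-((th - th0)^2 + (ph - ph0)^2) / w^2)
  surface_patch(
    function(th, ph) r0 + amp * e(th, ph),
    derivs = list(
      f_theta = function(th, ph) amp * e(th, ph) * (-2 * (th - th0) / w^2),
      f_phi = function(th, ph) amp * e(th, ph) * (-2 * (ph - ph0) / w^2),
      f_thetatheta = function(th, ph)
        amp * e(th, ph) * (4 * (th - th0)^2 / w^4 - 2 / w^2),
      f_phiphi = function(th, ph)
        amp * e(th, ph) * (4 * (ph - ph0)^2 / w^4 - 2 / w^2),
      f_thetaphi = function(th, ph)
        amp * e(th, ph) * 4 * (th - th0) * (ph - ph0) / w^4
    ),
    domain = domain)
}

#' @rdname builtin_patches
#' @export
patch_offset_sphere <- function(rho, c, domain = NULL) {
  stopifnot(rho > 0, c > rho)
  if (is.null(domain)) {
    half <- 0.8 * asin(rho / c)
    domain <- c(pi / 2 - half, pi / 2 + half, -half, half)
  }
  D <- c^2 - rho^2
  sc <- function(th, ph) c * cos(ph) * sin(th)   # direction . centre (+y axis)
  s_of <- function(v) sqrt(pmax(v^2 - D, 0))
  d1 <- function(scv, dsc) dsc * (1 - scv / s_of(scv))
  d2 <- function(scv, dsc_a, dsc_b, ddsc) {
    ddsc * (1 - scv / s_of(scv)) + dsc_a * dsc_b * D / s_of(scv)^3
  }
  surface_patch(
    function(th, ph) { v <- sc(th, ph); v - s_of(v) },
    derivs = list(
      f_theta = function(th, ph) d1(sc(th, ph), c * cos(ph) * cos(th)),
      f_phi = function(th, ph) d1(sc(th, ph), -c * sin(ph) * sin(th)),
      f_thetatheta = function(th, ph)
        d2(sc(th, ph), c * cos(ph) * cos(th), c * cos(ph) * cos(th),
           -c * cos(ph) * sin(th)),
      f_thetaphi = function(th, ph)
        d2(sc(th, ph), c * cos(ph) * cos(th), -c * sin(ph) * sin(th),
           -c * sin(ph) * cos(th)),
      f_phiphi = function(th, ph)
        d2(sc(th, ph), -c * sin(ph) * sin(th), -c * sin(ph) * sin(th),
           -c * cos(ph) * sin(th))
    ),
    domain = domain)
}

patch_eval <- function(patch, th, ph) {
  list(f = patch$f(th, ph),
       ft = patch$d$f_theta(th, ph),
       fp = patch$d$f_phi(th, ph),
       ftt = patch$d$f_thetatheta(th, ph),
       fpp = patch$d$f_phiphi(th, ph),
       ftp = patch$d$f_thetaphi(th, ph))
}

#' Tangent frame and unit normal of a surface patch
#'
#' The embedding partials span the tangent plane: in angular components
#' `X_theta = (f_theta, 1, 0)` and `X_phi = (f_phi, 0, 1)`. The normal
#' direction is their cross product in the Cartesian chart (the metric is
#' conformal to the Euclidean one, so Euclidean orthogonality is metric
#' orthogonality); it is normalised to unit metric length and oriented
#' towards increasing `r` (away from the egocentre).
#'
#' @param patch A `surface_patch`.
#' @param theta,phi Interior parameter point.
#' @param euclidean If `TRUE`, normalise with the flat ambient metric.
#' @return List with `q` (base point), `X_theta`, `X_phi`, `n` (all
#'   [tangent_vector()]s in the angular basis).
#' @export
surface_frame <- function(patch, theta, phi, euclidean = FALSE) {
  stopifnot(inherits(patch, "surface_patch"))
  pe <- patch_eval(patch, theta, phi)
  if (pe$f <= 0) stop("patch has non-positive radius at this point.")
  q <- cyclopean_point(pe$f, theta, phi)
  X1 <- tangent_vector(pe$ft, 1, 0, "angular")
  X2 <- tangent_vector(pe$fp, 0, 1, "angular")
  x1 <- convert_basis(X1, q, "cartesian")$v
  x2 <- convert_basis(X2, q, "cartesian")$v
  N <- c(x1[2] * x2[3] - x1[3] * x2[2],
         x1[3] * x2[1] - x1[1] * x2[3],
         x1[1] * x2[2] - x1[2] * x2[1])
  nN <- sqrt(sum(N^2))
  if (nN < 1e-12 * sqrt(sum(x1^2)) * sqrt(sum(x2^2))) {
    stop("degenerate frame: embedding partials are parallel.")
  }
  radial <- as.numeric(as_cartesian(q)) / q$r
  if (sum(N * radial) < 0) N <- -N
  nv <- tangent_vector(N[1], N[2], N[3], "cartesian")
  nrm <- metric_norm(q, nv, euclidean = euclidean)
  nv <- tangent_vector(N[1] / nrm, N[2] / nrm, N[3] / nrm, "cartesian")
  list(q = q, X_theta = X1, X_phi = X2,
       n = convert_basis(nv, q, "angular"))
}

#' Shape operator, principal curvatures and local shape class
#'
#' Builds the scalar second fundamental form
#' `h(X_a, X_b) = <nabla_{X_a} X_b, n>_g` from covariant derivatives in
#' the ambient manifold (spherical-chart connection), solves the
#' g-symmetric 2x2 eigenproblem `S E_i = kappa_i E_i`, and reports the
#' principal curvatures `kappa1 >= kappa2`, g-orthonormal principal
#' directions, mean curvature `H`, perceived curvature `K = kappa1 kappa2`
#' and the local shape class of the (H, K) sign table. The perceived
#' curvature satisfies the Gauss relation `kappa1 kappa2 = K_induced -
#' K_ambient` (see [induced_gaussian_curvature()] and
#' [ambient_sectional_curvature()]).
#'
#' With `euclidean = TRUE` the ambient manifold is the flat outside world,
#' recovering classical surface geometry (e.g. a cylinder has `K = 0`,
#' `H != 0`).
#'
#' @param patch A `surface_patch`.
#' @param theta,phi Evaluation point.
#' @param euclidean Ambient choice.
#' @return An object of class `shape_result`.
#' @export
shape_operator <- function(patch, theta, phi, euclidean = FALSE) {
  fr <- surface_frame(patch, theta, phi, euclidean = euclidean)
  q <- fr$q
  pe <- patch_eval(patch, theta, phi)
  g <- metric_of(q, "angular", euclidean = euclidean)
  gamma <- christoffel_angular(q, euclidean = euclidean)$gamma
  X <- cbind(c(pe$ft, 1, 0), c(pe$fp, 0, 1))
  # coordinate second derivatives of the embedding (theta,phi) -> (r,theta,phi)
  DX <- list(matrix(c(pe$ftt, 0, 0, pe$ftp, 0, 0), 3, 2),   # d/dtheta of X1, X2
             matrix(c(pe$ftp, 0, 0, pe$fpp, 0, 0), 3, 2))   # d/dphi of X1, X2
  nv <- fr$n$v
  hmat <- matrix(0, 2, 2)
  for (a in 1:2) for (b in 1:2) {
    cov <- DX[[a]][, b]
    for (i in 1:3) {
      cov[i] <- cov[i] + as.numeric(X[, a] %*% gamma[i, , ] %*% X[, b])
    }
    hmat[a, b] <- as.numeric(cov %*% g %*% nv)
  }
  hmat <- (hmat + t(hmat)) / 2
  gt <- t(X) %*% g %*% X
  if (rcond_2x2(gt) < 1e-12) stop("induced metric is numerically singular.")
  U <- chol(gt)
  W <- solve(t(U), t(solve(t(U), t(hmat))))
  ev <- eigen(W, symmetric = TRUE)
  kappa <- ev$values                     # decreasing: kappa1 >= kappa2
  wpar <- solve(U, ev$vectors)           # param-coordinate eigenvectors
  mk_dir <- function(wcol) {
    e <- as.numeric(X %*% wcol)
    tv <- tangent_vector(e[1], e[2], e[3], "angular")
    nrm <- metric_norm(q, tv, euclidean = euclidean)
    tangent_vector(e[1] / nrm, e[2] / nrm, e[3] / nrm, "angular")
  }
  H <- mean(kappa)
  K <- kappa[1] * kappa[2]
  structure(list(kappa1 = kappa[1], kappa2 = kappa[2],
                 E1 = mk_dir(wpar[, 1]), E2 = mk_dir(wpar[, 2]),
                 H = H, K_prod = K,
                 shape_class = classify_shape(H, K),
                 h = hmat, induced_metric = gt, q = q, n = fr$n,
                 euclidean = euclidean),
            class = "shape_result")
}

rcond_2x2 <- function(m) {
  s <- svd(m)$d
  if (s[1] == 0) 0 else s[2] / s[1]
}

#' @export
print.shape_result <- function(x, ...) {
  cat(sprintf(paste0("<shape result at %s>\n  kappa1 = %.6g, kappa2 = %.6g, ",
                     "H = %.6g, K = %.6g  [%s]\n"),
              format(x$q), x$kappa1, x$kappa2, x$H, x$K_prod, x$shape_class))
  invisible(x)
}

#' Local shape class from mean and Gaussian curvature signs
#'
#' Sign-table taxonomy: `K > 0` elliptic (`cap` for `H < 0`, `cup` for
#' `H > 0`, with the normal oriented away from the egocentre); `K < 0`
#' `saddle` (or `symmetric saddle` when `H = 0`); `K = 0` parabolic
#' (`ridge`/`valley` by the sign of `H`) or `planar` when both vanish.
#' Zeros are decided within a tolerance band `eps`.
#'
#' @param H Mean curvature.
#' @param K_prod Product of principal curvatures.
#' @param eps Zero band.
#' @return A character label.
#' @export
classify_shape <- function(H, K_prod, eps = 1e-8) {
  stopifnot(is.finite(H), is.finite(K_prod))
  if (abs(K_prod) <= eps) {
    if (abs(H) <= eps) "planar" else if (H < 0) "ridge" else "valley"
  } else if (K_prod > 0) {
    if (H < 0) "cap" else "cup"
  } else {
    if (abs(H) <= eps) "symmetric saddle" else "saddle"
  }
}

induced_metric_at <- function(patch, th, ph, euclidean = FALSE) {
  pe <- patch_eval(patch, th, ph)
  q <- cyclopean_point(pe$f, th, ph)
  g <- metric_of(q, "angular", euclidean = euclidean)
  X <- cbind(c(pe$ft, 1, 0), c(pe$fp, 0, 1))
  t(X) %*% g %*% X
}

#' Intrinsic Gaussian curvature of the induced metric (Brioschi formula)
#'
#' Evaluates the Gaussian curvature of the pulled-back 2D metric directly
#' from the metric components `E, F, G` and their parameter derivatives
#' (nested central differences), independently of the shape-operator
#' pipeline. Used as the second route of the Gauss-relation check
#' `kappa1 kappa2 = K_induced - K_ambient`.
#'
#' @param patch A `surface_patch`.
#' @param theta,phi Evaluation point.
#' @param euclidean Ambient choice for the pullback.
#' @param h Finite-difference step in the parameters.
#' @param richardson If `TRUE`, eliminate the leading O(h^2) error by a
#'   second evaluation at `h/2` (Richardson extrapolation).
#' @return Scalar Gaussian curvature.
#' @export
induced_gaussian_curvature <- function(patch, theta, phi, euclidean = FALSE,
                                       h = 2e-4, richardson = TRUE) {
  if (richardson) {
    k1 <- induced_gaussian_curvature(patch, theta, phi, euclidean, h,
                                     richardson = FALSE)
    k2 <- induced_gaussian_curvature(patch, theta, phi, euclidean, h / 2,
                                     richardson = FALSE)
    return((4 * k2 - k1) / 3)
  }
  m <- function(th, ph) induced_metric_at(patch, th, ph, euclidean)
  comp <- function(th, ph) { g <- m(th, ph); c(E = g[1, 1], F = g[1, 2], G = g[2, 2]) }
  c0 <- comp(theta, phi)
  cu_p <- comp(theta + h, phi); cu_m <- comp(theta - h, phi)
  cv_p <- comp(theta, phi + h); cv_m <- comp(theta, phi - h)
  cpp <- comp(theta + h, phi + h); cpm <- comp(theta + h, phi - h)
  cmp <- comp(theta - h, phi + h); cmm <- comp(theta - h, phi - h)
  du <- (cu_p - cu_m) / (2 * h)
  dv <- (cv_p - cv_m) / (2 * h)
  duu <- (cu_p - 2 * c0 + cu_m) / h^2
  dvv <- (cv_p - 2 * c0 + cv_m) / h^2
  duv <- (cpp - cpm - cmp + cmm) / (4 * h^2)
  E <- c0["E"]; F <- c0["F"]; G <- c0["G"]
  M1 <- matrix(c(-dvv["E"] / 2 + duv["F"] - duu["G"] / 2, du["E"] / 2, du["F"] - dv["E"] / 2,
                 dv["F"] - du["G"] / 2, E, F,
                 dv["G"] / 2, F, G),
               3, 3, byrow = TRUE)
  M2 <- matrix(c(0, dv["E"] / 2, du["G"] / 2,
                 dv["E"] / 2, E, F,
                 du["G"] / 2, F, G),
               3, 3, byrow = TRUE)
  as.numeric((det(M1) - det(M2)) / (E * G - F^2)^2)
}
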