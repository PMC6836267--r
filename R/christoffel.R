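#' Christoffel symbols of the perceived metric (closed form)
#'
#' In the tangential-velocity frame, where the perceived metric is
#' `(1/r^2) I`, all symbols vanish except seven:
#' `G^1_11 = -1/r`, `G^1_22 = 1/r`, `G^1_33 = 1/r`,
#' `G^2_12 = G^2_21 = -1/r`, `G^3_13 = G^3_31 = -1/r`
#' (the symmetric pairs counted once). The array is indexed
#' `gamma[i, j, k]` for `G^i_jk` and is exactly symmetric in `j, k`.
#'
#' @param q A [cyclopean_point()].
#' @return An object of class `christoffel_array`: list with the 3x3x3
#'   `gamma`, the `basis` tag and the `point`.
#' @seealso [christoffel_numeric()] for the finite-difference evaluation
#'   from the metric and its inverse.
#' @export
#' @examples
#' christoffel_closed_form(cyclopean_point(2, 0, 0))$gamma[1, 1, 1]  # -0.5
christoffel_closed_form <- function(q) {
  stopifnot(inherits(q, "cyclopean_point"))
  g <- array(0, c(3, 3, 3))
  r <- q$r
  g[1, 1, 1] <- -1 / r
  g[1, 2, 2] <- 1 / r
  g[1, 3, 3] <- 1 / r
  g[2, 1, 2] <- g[2, 2, 1] <- -1 / r
  g[3, 1, 3] <- g[3, 3, 1] <- -1 / r
  structure(list(gamma = g, basis = "tangential", point = q),
            class = "christoffel_array")
}

# Closed-form Christoffel symbols of the angular (spherical-chart)
# coordinates, either for the perceived metric diag(1/r^2, cos^2 phi, 1)
# or for the Euclidean metric diag(1, r^2 cos^2 phi, r^2). These are the
# symbols the geodesic spray and the embedded-surface machinery use.
christoffel_angular <- function(q, euclidean = FALSE) {
  stopifnot(inherits(q, "cyclopean_point"))
  g <- array(0, c(3, 3, 3))
  r <- q$r; tp <- tan(q$phi); cp <- cos(q$phi); sp <- sin(q$phi)
  if (!euclidean) {
    g[1, 1, 1] <- -1 / r
    g[2, 2, 3] <- g[2, 3, 2] <- -tp
    g[3, 2, 2] <- sp * cp
  } else {
    g[1, 2, 2] <- -r * cp^2
    g[1, 3, 3] <- -r
    g[2, 1, 2] <- g[2, 2, 1] <- 1 / r
    g[2, 2, 3] <- g[2, 3, 2] <- -tp
    g[3, 1, 3] <- g[3, 3, 1] <- 1 / r
    g[3, 2, 2] <- sp * cp
  }
  structure(list(gamma = g, basis = "angular", point = q,
                 euclidean = euclidean),
            class = "christoffel_array")
}

#' @export
print.christoffel_array <- function(x, ...) {
  nz <- which(x$gamma != 0, arr.ind = TRUE)
  cat(sprintf("<christoffel array, %s basis at %s>  %d nonzero entries\n",
              x$basis, format(x$point), nrow(nz)))
  if (nrow(nz)) {
    for (row in seq_len(nrow(nz))) {
      i <- nz[row, 1]; j <- nz[row, 2]; k <- nz[row, 3]
      cat(sprintf("  G^%d_%d%d = %.6g\n", i, j, k, x$gamma[i, j, k]))
    }
  }
  invisible(x)
}

# Metric matrix as a function of the coordinate triple, per basis. In the
# tangential frame the components are treated as coordinates with the metric
# depending on x1 = r only, which is how the closed-form symbols above were
# derived.
metric_coord_fn <- function(basis, euclidean = FALSE) {
  if (basis == "tangential") {
    if (euclidean) function(x) diag(3) else function(x) diag(3) / x[1]^2
  } else if (basis == "angular") {
    if (euclidean) {
      function(x) diag(c(1, x[1]^2 * cos(x[3])^2, x[1]^2))
    } else {
      function(x) diag(c(1 / x[1]^2, cos(x[3])^2, 1))
    }
  } else {
    stop("numeric Christoffel evaluation supports 'tangential' and 'angular' bases.")
  }
}

#' Christoffel symbols by central differences of the metric
#'
#' Evaluates `G^i_jk = (1/2) g^{im} (d_k g_mj + d_j g_mk - d_m g_jk)` with
#' central finite differences of the metric components, as a numerical
#' cross-check of [christoffel_closed_form()]. The default step is
#' `1e-5 * max(r, 1)` for the radial coordinate, which balances truncation
#' against rounding for the `1/r` metric family.
#'
#' @param q A [cyclopean_point()].
#' @param h Step size; default `1e-5 * max(r, 1)`.
#' @param basis `"tangential"` (default, the frame of the closed form) or
#'   `"angular"`.
#' @param euclidean If `TRUE`, symbols of the flat outside-world metric.
#' @return A `christoffel_array`.
#' @export
christoffel_numeric <- function(q, h = NULL, basis = c("tangential", "angular"),
                                euclidean = FALSE) {
  stopifnot(inherits(q, "cyclopean_point"))
  basis <- match.arg(basis)
  if (is.null(h)) h <- 1e-5 * max(q$r, 1)
  gfun <- metric_coord_fn(basis, euclidean)
  x <- c(q$r, q$theta, q$phi)
  g0 <- gfun(x)
  ginv <- solve(g0)
  # dg[m, j, k] = d g_mj / d x_k
  dg <- array(0, c(3, 3, 3))
  for (k in 1:3) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + h; xm[k] <- xm[k] - h
    dg[, , k] <- (gfun(xp) - gfun(xm)) / (2 * h)
  }
  gamma <- array(0, c(3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    s <- 0
    for (m in 1:3) {
      s <- s + ginv[i, m] * (dg[m, j, k] + dg[m, k, j] - dg[j, k, m])
    }
    gamma[i, j, k] <- s / 2
  }
  structure(list(gamma = gamma, basis = basis, point = q,
                 euclidean = euclidean),
            class = "christoffel_array")
}

#' Count nonzero Christoffel symbols
#'
#' Counts the nonzero entries of the 27-entry array (symmetric entries
#' `G^i_jk` and `G^i_kj` count separately, as in the printed list of
#' seven). A component counts as zero when `|G| * r < eps_scaled`, a
#' scale-free threshold for the `1/r` family.
#'
#' @param ch A `christoffel_array`.
#' @param eps_scaled Scale-free zero threshold.
#' @return Integer count.
#' @export
christoffel_nonzero_count <- function(ch, eps_scaled = 1e-9) {
  stopifnot(inherits(ch, "christoffel_array"))
  sum(abs(ch$gamma) * ch$point$r >= eps_scaled)
}
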