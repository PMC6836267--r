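signed_angle_xy <- function(from, to) {
  # ccw-positive angle from 'from' to 'to' in the horizontal plane (seen
  # from +z)
  atan2(from[1] * to[2] - from[2] * to[1], from[1] * to[1] + from[2] * to[2])
}

deviation_row <- function(task, deviation, a, b) {
  xa <- as.numeric(as_cartesian(a)); xb <- as.numeric(as_cartesian(b))
  ra <- sqrt(sum(xa^2)); rb <- sqrt(sum(xb^2))
  sep <- acos(min(1, max(-1, sum(xa * xb) / (ra * rb))))
  out <- tibble::tibble(task = task, deviation_rad = deviation,
                        separation_angle = sep, relative_distance = rb / ra)
  structure(out, class = c("deviation_result", class(out)))
}

#' Exocentric pointing error predicted by the warped geometry
#'
#' A pointer at one location aimed at a target appears correctly aligned
#' when it points along the connecting geodesic's initial velocity, which
#' is perceived as the straight-line direction. The predicted error is the
#' angle between the veridical Euclidean direction (pointer to target) and
#' that initial tangent, evaluated in the shared Cartesian chart;
#' counterclockwise (seen from +z) is positive. Radially aligned pairs
#' give zero error (radial geodesics are Euclidean-straight); the error is
#' mirror-antisymmetric and grows with the separation angle at the
#' egocentre.
#'
#' @param pointer,target Points in the horizontal plane (any point
#'   representation).
#' @param ... Passed to [two_point_geodesic()].
#' @return A one-row tibble of class `deviation_result` with columns
#'   `task, deviation_rad, separation_angle, relative_distance`.
#' @export
pointing_error <- function(pointer, target, ...) {
  pointer <- as_cyclopean(pointer); target <- as_cyclopean(target)
  geo <- two_point_geodesic(pointer, target, ...)
  v0 <- trajectory_tangent(geo, "initial")$v$v
  chord <- as.numeric(as_cartesian(target)) - as.numeric(as_cartesian(pointer))
  deviation_row("pointing", signed_angle_xy(chord, v0), pointer, target)
}

#' Gaze-averaged exocentric pointing error
#'
#' Models the strategy of looking back and forth: the perceived direction
#' estimated at the pointer (the geodesic's initial tangent) is averaged
#' with the negated perceived direction estimated at the target (the
#' negated terminal tangent, compared as a Euclidean direction in the
#' shared chart), both taken as unit vectors; optionally the averaging is
#' iterated. The averaged direction is closer to veridical than either
#' single estimate.
#'
#' @inheritParams pointing_error
#' @param iterations Number of averaging passes (the default single pass
#'   already captures the equal-weight strategy; further passes re-average
#'   with the same two estimates and leave the result unchanged, so this
#'   is exposed only for strategy exploration).
#' @return A `deviation_result` row with `task = "averaged-pointing"`.
#' @export
averaged_pointing_error <- function(pointer, target, iterations = 1L, ...) {
  pointer <- as_cyclopean(pointer); target <- as_cyclopean(target)
  geo <- two_point_geodesic(pointer, target, ...)
  # the direction estimated while looking at the target is the perceived
  # straight line from target back to pointer, i.e. minus the terminal
  # tangent; the strategy negates it again before averaging, so the
  # terminal tangent enters with a plus sign
  v0 <- trajectory_tangent(geo, "initial")$v$v
  v1 <- trajectory_tangent(geo, "terminal")$v$v
  u0 <- v0 / sqrt(sum(v0^2))
  u1 <- v1 / sqrt(sum(v1^2))
  avg <- u0 + u1
  for (i in seq_len(max(0L, iterations - 1L))) avg <- avg / 2 + (u0 + u1) / 4
  chord <- as.numeric(as_cartesian(target)) - as.numeric(as_cartesian(pointer))
  deviation_row("averaged-pointing", signed_angle_xy(chord, avg),
                pointer, target)
}

#' Collinearity-task error
#'
#' Setting a rod at one location to appear collinear with a rod at another
#' uses the same back-and-forth direction estimates as averaged exocentric
#' pointing; the predicted deviation surface is the same up to the rod
#' orientation convention.
#'
#' @inheritParams averaged_pointing_error
#' @return A `deviation_result` row with `task = "collinearity"`.
#' @export
collinearity_error <- function(pointer, target, ...) {
  out <- averaged_pointing_error(pointer, target, ...)
  out$task <- "collinearity"
  out
}

#' Parallelity-task error via parallel transport
#'
#' A reference rod direction at `a`, parallel-transported along the
#' connecting geodesic to `b`, is perceived as parallel to the reference;
#' the predicted deviation is the Euclidean angle between the transported
#' direction and the original direction (ccw-positive seen from +z). In
#' the horizontal plane parallel transport rotates every vector by the
#' same angle, so the deviation is independent of the rod orientation; it
#' passes through zero at zero separation and is mirror-antisymmetric,
#' and across placement grids it is substantially larger than the
#' averaged-pointing deviation.
#'
#' @param a,b Reference and test locations.
#' @param rod_angle Orientation of the reference rod, radians ccw from +x.
#' @param cadence Sampling of the transport curve.
#' @param ... Passed to [two_point_geodesic()].
#' @return A `deviation_result` row with `task = "parallelity"`.
#' @export
parallelity_error <- function(a, b, rod_angle = pi / 2, cadence = 0.02, ...) {
  a <- as_cyclopean(a); b <- as_cyclopean(b)
  geo <- two_point_geodesic(a, b, cadence = cadence, ...)
  rod <- c(cos(rod_angle), sin(rod_angle), 0)
  qa <- cyclopean_point(geo$r[1], geo$theta[1], geo$phi[1])
  v0 <- convert_basis(tangent_vector(rod[1], rod[2], rod[3], "cartesian"),
                      qa, "angular")
  tr <- parallel_transport(geo, v0)
  last <- nrow(tr)
  qb <- cyclopean_point(geo$r[last], geo$theta[last], geo$phi[last])
  vT <- convert_basis(tangent_vector(tr$g1[last], tr$g2[last], tr$g3[last],
                                     "angular"), qb, "cartesian")$v
  deviation_row("parallelity", signed_angle_xy(rod, vT), a, b)
}

#' Deviation surface over a placement grid
#'
#' Runs one of the task simulators over a grid of pointer/target
#' placements in the horizontal plane: the pointer sits at
#' `(r_pointer, -separation/2)` and the target at
#' `(r_target, +separation/2)` in `(r, theta)`.
#'
#' @param r_pointer,r_target Radii (metres), recycled over the grid.
#' @param separations Separation angles at the egocentre (radians).
#' @param mode One of `"pointing"`, `"averaged"`, `"parallelity"`,
#'   `"collinearity"`.
#' @param ... Passed to the task simulator.
#' @return A tibble with one `deviation_result` row per grid cell plus
#'   `r_pointer, r_target, separation` columns.
#' @export
pointing_grid <- function(r_pointer = c(1, 2, 4), r_target = r_pointer,
                          separations = c(0.2, 0.4, 0.8),
                          mode = c("pointing", "averaged", "parallelity",
                                   "collinearity"),
                          ...) {
  mode <- match.arg(mode)
  fn <- switch(mode,
               pointing = pointing_error,
               averaged = averaged_pointing_error,
               parallelity = parallelity_error,
               collinearity = collinearity_error)
  grid <- tidyr::expand_grid(r_pointer = r_pointer, r_target = r_target,
                             separation = separations)
  res <- purrr::pmap_dfr(grid, function(r_pointer, r_target, separation) {
    a <- cyclopean_point(r_pointer, -separation / 2, 0)
    b <- cyclopean_point(r_target, separation / 2, 0)
    dplyr::bind_cols(
      tibble::tibble(r_pointer = r_pointer, r_target = r_target,
                     separation = separation),
      fn(a, b, ...)
    )
  })
  structure(res, class = c("deviation_grid", class(res)), mode = mode)
}
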