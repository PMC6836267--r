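#' Head-eye configuration for horizontal-plane binocular geometry
#'
#' Planar (horizontal-slice) model of binocular fixation. The eyes'
#' rotation centres sit at `(-d/2, 0)` (left) and `(+d/2, 0)` (right) in
#' head coordinates, with the egocentre (their midpoint) at the origin and
#' straight ahead along +y. The nodal points lie `r_e` metres along each
#' optic axis from the rotation centre; the visual axis deviates from the
#' optic axis by the angle `alpha` towards the nose (about 5 degrees, 0.087
#' rad, in adults). All angles are counterclockwise-positive radians;
#' `theta_h` rotates the whole head, `theta_l`/`theta_r` rotate each eye
#' within the head relative to straight ahead.
#'
#' By default `theta_l`/`theta_r` are rotations of the optic axes with
#' `alpha` applied on top; `axes = "visual"` interprets them as visual-axis
#' rotations instead.
#'
#' @param d Inter-rotation-centre distance, metres (> 0).
#' @param r_e Rotation-centre-to-nodal-point distance, metres (>= 0).
#' @param alpha Optic/visual axis angle, radians.
#' @param theta_h Head angle, radians.
#' @param theta_l,theta_r Eye-in-head angles, radians.
#' @param axes `"optic"` or `"visual"`.
#' @return An object of class `head_eye_config`.
#' @export
head_eye_config <- function(d = 0.06, r_e = 0.007, alpha = 0,
                            theta_h = 0, theta_l = 0, theta_r = 0,
                            axes = c("optic", "visual")) {
  axes <- match.arg(axes)
  stopifnot(d > 0, r_e >= 0)
  structure(list(d = d, r_e = r_e, alpha = alpha, theta_h = theta_h,
                 theta_l = theta_l, theta_r = theta_r, axes = axes),
            class = "head_eye_config")
}

rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)

eye_geometry <- function(config) {
  with(config, {
    cl <- as.numeric(rot2(theta_h) %*% c(-d / 2, 0))
    cr <- as.numeric(rot2(theta_h) %*% c(d / 2, 0))
    base <- pi / 2 + theta_h  # straight ahead (+y) as a ccw angle from +x
    if (axes == "optic") {
      optic_l <- base + theta_l
      optic_r <- base + theta_r
      vis_l <- optic_l - alpha   # left visual axis deviates nasally (cw)
      vis_r <- optic_r + alpha   # right visual axis deviates nasally (ccw)
    } else {
      vis_l <- base + theta_l
      vis_r <- base + theta_r
      optic_l <- vis_l + alpha
      optic_r <- vis_r - alpha
    }
    nl <- cl + r_e * c(cos(optic_l), sin(optic_l))
    nr <- cr + r_e * c(cos(optic_r), sin(optic_r))
    list(c_l = cl, c_r = cr, n_l = nl, n_r = nr,
         vis_l = vis_l, vis_r = vis_r)
  })
}

intersect_rays <- function(p1, a1, p2, a2, tol = 1e-12) {
  u1 <- c(cos(a1), sin(a1)); u2 <- c(cos(a2), sin(a2))
  det <- u1[1] * (-u2[2]) - (-u2[1]) * u1[2]
  if (abs(det) < tol) return(NULL)
  rhs <- p2 - p1
  t1 <- (rhs[1] * (-u2[2]) - (-u2[1]) * rhs[2]) / det
  t2 <- (u1[1] * rhs[2] - rhs[1] * u1[2]) / det
  list(point = p1 + t1 * u1, t1 = t1, t2 = t2)
}

#' Cyclopean gaze vector from head/eye angles
#'
#' Intersects the two visual axes (rays through the nodal points) and
#' returns the fixation point `Q` with its cyclopean gaze coordinates
#' `(r, theta)` measured from the egocentre. Parallel or diverging axes
#' (no fixation in front of the eyes) raise an error.
#'
#' @param config A [head_eye_config()].
#' @return An object of class `gaze_result`: list with `Q`
#'   ([cartesian_point()], `z = 0`), `r`, `theta`, nodal points and
#'   visual-axis angles.
#' @export
#' @examples
#' cfg <- head_eye_config(d = 0.06, r_e = 0, alpha = 0,
#'                        theta_l = -0.03, theta_r = 0.03)
#' cyclopean_gaze(cfg)$r  # ~ (d/2) / tan(0.03)
cyclopean_gaze <- function(config) {
  stopifnot(inherits(config, "head_eye_config"))
  ge <- eye_geometry(config)
  hit <- intersect_rays(ge$n_l, ge$vis_l, ge$n_r, ge$vis_r)
  if (is.null(hit) || hit$t1 <= 0 || hit$t2 <= 0) {
    stop("no fixation: the visual axes are parallel or diverging.")
  }
  qpt <- hit$point
  structure(list(Q = cartesian_point(qpt[1], qpt[2], 0),
                 r = sqrt(sum(qpt^2)),
                 theta = atan2(qpt[2], qpt[1]),
                 nodal_l = ge$n_l, nodal_r = ge$n_r,
                 vis_l = ge$vis_l, vis_r = ge$vis_r,
                 config = config),
            class = "gaze_result")
}

#' @export
print.gaze_result <- function(x, ...) {
  cat(sprintf("<gaze result>  Q = (%.5g, %.5g) m;  r = %.5g m, theta = %.5g rad\n",
              x$Q[1], x$Q[2], x$r, x$theta))
  invisible(x)
}

#' Zero-disparity locus (horopter)
#'
#' Applies matched retinal offsets `delta` to both visual axes and
#' intersects the corresponding rays through the two nodal points: points
#' on the resulting locus project to corresponding retinal positions and
#' induce no disparity. The locus contains the fixation point (`delta =
#' 0`). With `alpha = 0` and `r_e = 0` it is the circle through the
#' fixation point and the two nodal points; it becomes flatter as fixation
#' distance grows. Near-parallel ray pairs are skipped and counted in the
#' `skipped` attribute.
#'
#' @param config A [head_eye_config()].
#' @param n_samples Number of `delta` samples.
#' @param delta_max Largest |retinal offset| in radians.
#' @return A tibble of class `horopter_curve` with columns
#'   `delta, x, y, r, theta`.
#' @export
horopter <- function(config, n_samples = 181, delta_max = 0.6) {
  gz <- cyclopean_gaze(config)  # validates fixation
  ge <- eye_geometry(config)
  deltas <- seq(-delta_max, delta_max, length.out = n_samples)
  skipped <- 0L
  rows <- lapply(deltas, function(dl) {
    hit <- intersect_rays(ge$n_l, ge$vis_l + dl, ge$n_r, ge$vis_r + dl,
                          tol = 1e-10)
    if (is.null(hit) || hit$t1 <= 0 || hit$t2 <= 0) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    p <- hit$point
    tibble::tibble(delta = dl, x = p[1], y = p[2],
                   r = sqrt(sum(p^2)), theta = atan2(p[2], p[1]))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("horopter_curve", class(out)),
            skipped = skipped, gaze = gz)
}

#' Retinal image size of a subtended angle
#'
#' In the reduced-eye model a ray through the nodal point reaches the
#' retina unbent, so the image size is the nodal-point-to-retina distance
#' (17.2 mm) times the subtended angle in radians.
#'
#' @param subtended_angle Angle in radians (>= 0, vectorised).
#' @param nodal_distance_mm Nodal-point-to-retina distance, millimetres.
#' @return Image size in millimetres.
#' @export
retinal_image_size <- function(subtended_angle, nodal_distance_mm = 17.2) {
  stopifnot(is.numeric(subtended_angle), all(subtended_angle >= 0))
  nodal_distance_mm * subtended_angle
}
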