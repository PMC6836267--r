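#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a geodesic trajectory
#'
#' @param x A `geodesic_trajectory`.
#' @param ... Unused.
#' @return A plain tibble of the samples.
#' @method tidy geodesic_trajectory
#' @export
tidy.geodesic_trajectory <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a geodesic trajectory
#'
#' @param x A `geodesic_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble: samples, duration, initial metric speed,
#'   relative speed drift, truncation flag.
#' @method glance geodesic_trajectory
#' @export
glance.geodesic_trajectory <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x),
                 duration = max(x$t),
                 gspeed = x$gspeed[1],
                 speed_drift = attr(x, "diagnostics")$speed_drift,
                 truncated = isTRUE(attr(x, "truncated")))
}

#' Tidy a shape-operator result
#'
#' @param x A `shape_result`.
#' @param ... Unused.
#' @return A one-row tibble with curvatures and shape class.
#' @method tidy shape_result
#' @export
tidy.shape_result <- function(x, ...) {
  tibble::tibble(kappa1 = x$kappa1, kappa2 = x$kappa2, H = x$H,
                 K = x$K_prod, shape_class = x$shape_class,
                 r = x$q$r, theta = x$q$theta, phi = x$q$phi)
}

#' Tidy a gaze result
#'
#' @param x A `gaze_result`.
#' @param ... Unused.
#' @return A one-row tibble with the fixation point and gaze coordinates.
#' @method tidy gaze_result
#' @export
tidy.gaze_result <- function(x, ...) {
  qx <- unname(x$Q[1]); qy <- unname(x$Q[2]); rr <- x$r; th <- x$theta
  tibble::tibble(x = qx, y = qy, r = rr, theta = th)
}

#' Tidy an occlusion-filling report
#'
#' @param x A `fill_report`.
#' @param ... Unused.
#' @return The per-pair classification table.
#' @method tidy fill_report
#' @export
tidy.fill_report <- function(x, ...) x$pairs

#' Overall coverage summary of an occlusion-filling report
#'
#' @param x A `fill_report`.
#' @param ... Unused.
#' @return A one-row tibble with mean coverage before/after filling.
#' @method glance fill_report
#' @export
glance.fill_report <- function(x, ...) {
  tibble::tibble(n_places = nrow(x$coverage),
                 mean_before = mean(x$coverage$before),
                 mean_after = mean(x$coverage$after))
}

#' @method autoplot horopter_curve
#' @export
autoplot.horopter_curve <- function(object, ...) {
  gz <- attr(object, "gaze")
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = gz$Q[1], y = gz$Q[2], shape = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' @method autoplot deviation_grid
#' @export
autoplot.deviation_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$separation, .data$deviation_rad,
                               colour = factor(.data$r_target / .data$r_pointer),
                               group = interaction(.data$r_pointer,
                                                   .data$r_target))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "separation angle (rad)", y = "deviation (rad)",
                  colour = "r_target / r_pointer") +
    ggplot2::theme_minimal()
}
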