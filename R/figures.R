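#' Reproduce the standard geodesic-family figures
#'
#' Re-runs the documented initial conditions of the trajectory figures
#' (36 directions at 10 degree spacing, 1 m/s launches, samples every
#' 500 ms) and returns both the underlying table and a ggplot:
#'
#' * `fig5a` / `fig5b` — planar families from (0, 1, 0) m and (0, 5, 0) m
#'   with initial velocities in the horizontal plane (log-spiral
#'   geodesics; divergence is stronger in the near field);
#' * `fig6a` — great-circle family on the 5 m visual sphere from
#'   (0, 5, 0) m, initial velocities normal to the gaze line;
#' * `fig6b` — the same construction from the elevated point
#'   (0, 3.54, 3.54) m;
#' * `fig7a` — the tilted case from (0, 3.54, 3.54) m with velocities in
#'   the xz-plane (neither plane- nor sphere-confined);
#' * `fig8` — the totally geodesic coordinate grid of the horizontal
#'   plane (radial and circular geodesics) next to its image under the
#'   conformal log map `(r, theta) -> (log r, theta)`, where both grid
#'   families become straight lines.
#'
#' @param name Figure name.
#' @param n_directions,cadence Family parameters.
#' @return An object of class `vm_figure`: list with `name`, `data` and
#'   `plot`.
#' @export
reproduce_figure <- function(name = c("fig5a", "fig5b", "fig6a", "fig6b",
                                      "fig7a", "fig8"),
                             n_directions = 36, cadence = 0.5) {
  name <- match.arg(name)
  fam_fig <- function(q0, e1, e2, duration, view) {
    fam <- geodesic_family(q0, e1, e2, n_directions = n_directions,
                           duration = duration, cadence = cadence,
                           speed = "euclidean")
    list(data = tibble::as_tibble(fam),
         plot = plot_family(fam, view = view))
  }
  out <- switch(name,
    fig5a = fam_fig(c(0, 1, 0), c(1, 0, 0), c(0, 1, 0), 2, "xy"),
    fig5b = fam_fig(c(0, 5, 0), c(1, 0, 0), c(0, 1, 0), 10, "xy"),
    fig6a = fam_fig(c(0, 5, 0), c(1, 0, 0), c(0, 0, 1), 32, "xz"),
    fig6b = fam_fig(cartesian_point(0, 5 / sqrt(2), 5 / sqrt(2)),
                    c(1, 0, 0), c(0, -1 / sqrt(2), 1 / sqrt(2)), 32, "xz"),
    fig7a = fam_fig(cartesian_point(0, 5 / sqrt(2), 5 / sqrt(2)),
                    c(1, 0, 0), c(0, 0, 1), 32, "xz"),
    fig8 = geodesic_grid_figure()
  )
  structure(c(list(name = name), out), class = "vm_figure")
}

#' @export
print.vm_figure <- function(x, ...) {
  cat(sprintf("<figure %s>  %d rows of trajectory data\n", x$name,
              nrow(x$data)))
  print(x$plot)
  invisible(x)
}

#' Plot a geodesic family
#'
#' @param fam A [geodesic_family()] result.
#' @param view Projection plane: `"xy"`, `"xz"` or `"yz"`.
#' @return A ggplot.
#' @export
plot_family <- function(fam, view = c("xy", "xz", "yz")) {
  view <- match.arg(view)
  ax <- strsplit(view, "")[[1]]
  ggplot2::ggplot(fam, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                                    group = .data$traj_id)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste(ax[1], "(m)"), y = paste(ax[2], "(m)")) +
    ggplot2::theme_minimal()
}

#' @method autoplot geodesic_family
#' @export
autoplot.geodesic_family <- function(object, view = "xy", ...) {
  plot_family(object, view = view)
}

geodesic_grid_figure <- function(radii = exp(seq(log(0.25), log(4), length.out = 9)),
                                 angles = seq(0, 330, by = 30) * pi / 180) {
  arc_t <- seq(0, 2 * pi, length.out = 121)
  circles <- purrr::map_dfr(seq_along(radii), function(i) {
    tibble::tibble(family = "circular", id = paste0("c", i),
                   x = radii[i] * cos(arc_t), y = radii[i] * sin(arc_t),
                   u = log(radii[i]), theta = arc_t)
  })
  rr <- seq(min(radii), max(radii), length.out = 61)
  radials <- purrr::map_dfr(seq_along(angles), function(i) {
    tibble::tibble(family = "radial", id = paste0("r", i),
                   x = rr * cos(angles[i]), y = rr * sin(angles[i]),
                   u = log(rr), theta = angles[i])
  })
  dat <- dplyr::bind_rows(circles, radials)
  long <- dplyr::bind_rows(
    dplyr::transmute(dat, panel = "outside world", id = .data$id,
                     family = .data$family, h = .data$x, v = .data$y),
    dplyr::transmute(dat, panel = "perceived (log map)", id = .data$id,
                     family = .data$family, h = .data$theta, v = .data$u)
  )
  plot <- ggplot2::ggplot(long, ggplot2::aes(.data$h, .data$v,
                                             group = .data$id,
                                             colour = .data$family)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  list(data = dat, plot = plot)
}
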