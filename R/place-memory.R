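#' Gaze-based visuospatial memory (G-memory)
#'
#' A sparse store of paired left/right image-point vectors keyed by
#' quantised cyclopean coordinates. The grid uses logarithmic radial bins
#' (constant perceived-distance width `d_lnr`, default 0.05, matching the
#' logarithmic structure of perceived depth) and angular bins of `d_ang`
#' radians (default 1 degree). Empty sites mean transparent or occluded
#' points (zero image-point vectors); stored pairs are retrievable exactly
#' by their accession coordinates.
#'
#' The store is an environment, so [gm_store()] updates it in place and
#' also returns it invisibly.
#'
#' @param d_lnr Radial bin width in log-distance.
#' @param d_ang Angular bin width, radians.
#' @param dim Image-point vector dimension (30 feature amplitudes).
#' @return An object of class `g_memory`.
#' @export
g_memory <- function(d_lnr = 0.05, d_ang = pi / 180, dim = 30L) {
  stopifnot(d_lnr > 0, d_ang > 0, dim >= 1L)
  structure(list(store = new.env(parent = emptyenv()),
                 d_lnr = d_lnr, d_ang = d_ang, dim = as.integer(dim)),
            class = "g_memory")
}

gm_key <- function(mem, q) {
  q <- as_cyclopean(q)
  sprintf("%d:%d:%d",
          as.integer(round(log(q$r) / mem$d_lnr)),
          as.integer(round(q$theta / mem$d_ang)),
          as.integer(round(q$phi / mem$d_ang)))
}

#' Store an image-point vector pair at a cyclopean site
#'
#' Empty sites are always written. An occupied site is overwritten only if
#' the Euclidean norm of the stored left/right difference vector is
#' strictly larger than that of the incoming pair — the incoming pair was
#' seen closer to the fovea, where the two eyes' features agree better.
#' Ties keep the existing entry.
#'
#' @param mem A [g_memory()].
#' @param q Site coordinates (any point representation).
#' @param sigma_l,sigma_r Numeric feature vectors of length `mem$dim`.
#' @return The memory, invisibly; attribute `written` on the return value
#'   reports whether the site changed.
#' @export
gm_store <- function(mem, q, sigma_l, sigma_r) {
  stopifnot(inherits(mem, "g_memory"))
  if (length(sigma_l) != mem$dim || length(sigma_r) != mem$dim) {
    stop("image-point vectors must have dimension ", mem$dim, ".")
  }
  q <- as_cyclopean(q)
  key <- gm_key(mem, q)
  new_diff <- sqrt(sum((sigma_l - sigma_r)^2))
  cur <- mem$store[[key]]
  written <- is.null(cur) || cur$diff > new_diff
  if (written) {
    mem$store[[key]] <- list(q = q, sigma_l = as.numeric(sigma_l),
                             sigma_r = as.numeric(sigma_r), diff = new_diff)
  }
  out <- mem
  attr(out, "written") <- written
  invisible(out)
}

#' Retrieve the pair stored at a site
#'
#' @param mem A [g_memory()].
#' @param q Accession coordinates.
#' @return List with `sigma_l`, `sigma_r` (and the stored `q`), or `NULL`
#'   for an empty (transparent/occluded) site.
#' @export
gm_retrieve <- function(mem, q) {
  stopifnot(inherits(mem, "g_memory"))
  mem$store[[gm_key(mem, q)]]
}

#' Number of occupied sites
#' @param mem A [g_memory()].
#' @return Integer.
#' @export
gm_size <- function(mem) length(ls(mem$store))

gm_clone <- function(mem) {
  out <- g_memory(d_lnr = mem$d_lnr, d_ang = mem$d_ang, dim = mem$dim)
  for (key in ls(mem$store)) out$store[[key]] <- mem$store[[key]]
  out
}

#' @export
print.g_memory <- function(x, ...) {
  cat(sprintf("<G-memory>  %d occupied sites (d_lnr = %.3g, d_ang = %.3g rad, dim %d)\n",
              gm_size(x), x$d_lnr, x$d_ang, x$dim))
  invisible(x)
}

#' Vector-bundle morphism, position part
#'
#' Moving the head from place `p_i` to `p_j` translates every perceived
#' image point by the opposite displacement:
#' `q_pj = q_pi - (p_j - p_i)` in Cartesian coordinates. The map is
#' invertible (swap the places); a head moved onto the image point leaves
#' no direction and is rejected.
#'
#' @param q Image-point position relative to place `p_i` (any point
#'   representation).
#' @param p_i,p_j Head places, Cartesian numeric length 3 (or
#'   [cartesian_point()]).
#' @return A [cyclopean_point()] relative to place `p_j`.
#' @export
morphism_H1 <- function(q, p_i, p_j) {
  x <- as.numeric(as_cartesian(q)) - (as.numeric(p_j) - as.numeric(p_i))
  if (sqrt(sum(x^2)) < 1e-12) {
    stop("head placed onto the image point: translated position has r = 0.")
  }
  cartesian_to_spherical(x)
}

#' Vector-bundle morphism, feature part
#'
#' Linear map carrying an image-point vector stored at radial distance
#' `r_i` to the corresponding vector at distance `r_j`. It depends only on
#' the radial pair (the metric is constant on visual spheres, so moves
#' within one sphere leave feature vectors invariant: the map is the
#' identity when `r_i = r_j`). The default family is the scalar scaling
#' `(r_i / r_j) I`, which composes consistently
#' (`H2(r2, r3) H2(r1, r2) = H2(r1, r3)`); any radial-pair-indexed linear
#' map can be plugged in via `family`.
#'
#' @param r_i,r_j Radial distances (> 0).
#' @param dim Feature dimension.
#' @param family Optional function `(r_i, r_j, dim) -> dim x dim matrix`.
#' @return A `dim` x `dim` matrix.
#' @export
morphism_H2 <- function(r_i, r_j, dim = 30L, family = NULL) {
  stopifnot(r_i > 0, r_j > 0)
  if (is.null(family)) {
    (r_i / r_j) * diag(dim)
  } else {
    m <- family(r_i, r_j, dim)
    stopifnot(is.matrix(m), all(dim(m) == c(dim, dim)))
    m
  }
}

# ---- synthetic scenes ------------------------------------------------------

#' Synthetic scene of opaque convex primitives
#'
#' Builds a scene of opaque spheres and axis-aligned boxes, samples points
#' on their surfaces, and attaches to each sample a fixed 30-component
#' base feature vector (seeded Gaussian). A point viewed from distance `r`
#' yields the stored image-point vector `base / r`, so transported vectors
#' under the default [morphism_H2()] family agree exactly with directly
#' viewed ones and fill accuracy is well defined.
#'
#' @param primitives List of primitives: `list(type = "sphere", centre,
#'   radius)` or `list(type = "box", lo, hi)`.
#' @param n_per_primitive Surface samples per primitive.
#' @param dim Feature dimension.
#' @param seed Seed for surface sampling and base features.
#' @return An object of class `vm_scene`: list with the primitives, a
#'   points tibble (`id, x, y, z, primitive`) and the base feature matrix.
#' @export
scene_fixture <- function(primitives, n_per_primitive = 120L, dim = 30L,
                          seed = 42L) {
  set.seed(seed)
  pts <- purrr::imap_dfr(primitives, function(pr, idx) {
    if (pr$type == "sphere") {
      u <- matrix(stats::rnorm(3 * n_per_primitive), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      tibble::tibble(x = pr$centre[1] + pr$radius * u[, 1],
                     y = pr$centre[2] + pr$radius * u[, 2],
                     z = pr$centre[3] + pr$radius * u[, 3],
                     primitive = idx)
    } else if (pr$type == "box") {
      lo <- pr$lo; hi <- pr$hi; ext <- hi - lo
      areas <- c(ext[2] * ext[3], ext[2] * ext[3], ext[1] * ext[3],
                 ext[1] * ext[3], ext[1] * ext[2], ext[1] * ext[2])
      face <- sample.int(6, n_per_primitive, replace = TRUE,
                         prob = areas / sum(areas))
      u <- stats::runif(n_per_primitive); v <- stats::runif(n_per_primitive)
      m <- t(vapply(seq_len(n_per_primitive), function(i) {
        switch(face[i],
               c(lo[1], lo[2] + u[i] * ext[2], lo[3] + v[i] * ext[3]),
               c(hi[1], lo[2] + u[i] * ext[2], lo[3] + v[i] * ext[3]),
               c(lo[1] + u[i] * ext[1], lo[2], lo[3] + v[i] * ext[3]),
               c(lo[1] + u[i] * ext[1], hi[2], lo[3] + v[i] * ext[3]),
               c(lo[1] + u[i] * ext[1], lo[2] + v[i] * ext[2], lo[3]),
               c(lo[1] + u[i] * ext[1], lo[2] + v[i] * ext[2], hi[3]))
      }, numeric(3)))
      tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3], primitive = idx)
    } else {
      stop("unknown primitive type: ", pr$type)
    }
  })
  pts$id <- seq_len(nrow(pts))
  base <- matrix(stats::rnorm(nrow(pts) * dim), nrow = nrow(pts))
  structure(list(primitives = primitives,
                 points = pts[, c("id", "x", "y", "z", "primitive")],
                 base = base, dim = as.integer(dim)),
            class = "vm_scene")
}

ray_hit_distance <- function(primitive, origin, dir) {
  # smallest positive distance along unit 'dir' from 'origin', or Inf
  if (primitive$type == "sphere") {
    oc <- origin - primitive$centre
    b <- sum(oc * dir)
    disc <- b^2 - (sum(oc^2) - primitive$radius^2)
    if (disc < 0) return(Inf)
    t1 <- -b - sqrt(disc)
    t2 <- -b + sqrt(disc)
    if (t1 > 1e-9) t1 else if (t2 > 1e-9) t2 else Inf
  } else {
    lo <- primitive$lo; hi <- primitive$hi
    tmin <- -Inf; tmax <- Inf
    for (k in 1:3) {
      if (abs(dir[k]) < 1e-15) {
        if (origin[k] < lo[k] || origin[k] > hi[k]) return(Inf)
      } else {
        ta <- (lo[k] - origin[k]) / dir[k]
        tb <- (hi[k] - origin[k]) / dir[k]
        tmin <- max(tmin, min(ta, tb))
        tmax <- min(tmax, max(ta, tb))
      }
    }
    if (tmax < max(tmin, 1e-9)) Inf else if (tmin > 1e-9) tmin else tmax
  }
}

#' Visibility of a scene point from a place
#'
#' Ray-casts from the place towards the point; the point is visible when
#' no opaque surface lies strictly nearer along the ray.
#'
#' @param scene A `vm_scene`.
#' @param place Cartesian head position (numeric length 3).
#' @param point_id Row id in `scene$points`.
#' @param eps Occlusion slack, metres.
#' @return Logical.
#' @export
scene_visible <- function(scene, place, point_id, eps = 1e-6) {
  p <- as.numeric(scene$points[point_id, c("x", "y", "z")])
  d <- p - as.numeric(place)
  dist <- sqrt(sum(d^2))
  if (dist < 1e-9) return(FALSE)
  u <- d / dist
  for (pr in scene$primitives) {
    t_hit <- ray_hit_distance(pr, as.numeric(place), u)
    if (t_hit < dist - eps) return(FALSE)
  }
  TRUE
}

#' Place-indexed bundle of G-memories over a scene
#'
#' Observes the scene from each head place: every visible surface sample
#' is stored into that place's G-memory at the cyclopean coordinates of
#' the point relative to the place, with image-point vectors `base / r`
#' (plus optional binocular noise on the right-eye copy). All member
#' memories share the grid resolution.
#'
#' @param scene A [scene_fixture()].
#' @param places List/matrix of Cartesian head positions.
#' @param d_lnr,d_ang Grid resolution, as in [g_memory()].
#' @param noise_sd Standard deviation of the binocular perturbation.
#' @param seed Seed for the noise draws.
#' @return An object of class `place_bundle`.
#' @export
place_bundle <- function(scene, places, d_lnr = 0.05, d_ang = pi / 180,
                         noise_sd = 0, seed = 1L) {
  stopifnot(inherits(scene, "vm_scene"))
  if (is.matrix(places)) places <- asplit(places, 1)
  set.seed(seed)
  memories <- lapply(places, function(p) {
    mem <- g_memory(d_lnr = d_lnr, d_ang = d_ang, dim = scene$dim)
    for (i in scene$points$id) {
      if (!scene_visible(scene, p, i)) next
      x <- as.numeric(scene$points[i, c("x", "y", "z")]) - as.numeric(p)
      r <- sqrt(sum(x^2))
      sig <- scene$base[i, ] / r
      sig_r <- sig + if (noise_sd > 0) stats::rnorm(scene$dim, sd = noise_sd) else 0
      mem <- gm_store(mem, cartesian_to_spherical(x), sig, sig_r)
    }
    mem
  })
  structure(list(scene = scene, places = lapply(places, as.numeric),
                 memories = memories),
            class = "place_bundle")
}

#' @export
print.place_bundle <- function(x, ...) {
  cat(sprintf("<place bundle>  %d places over %d scene points; occupied sites: %s\n",
              length(x$places), nrow(x$scene$points),
              paste(vapply(x$memories, gm_size, integer(1)), collapse = ", ")))
  invisible(x)
}

visibility_matrix <- function(bundle) {
  vapply(bundle$places, function(p) {
    vapply(bundle$scene$points$id, function(i) {
      scene_visible(bundle$scene, p, i)
    }, logical(1))
  }, logical(nrow(bundle$scene$points)))
}

#' Occlusion filling between place-encoded memories
#'
#' For every ordered pair of places, classifies each scene point as
#' `(++)` (visible from both), `(+-)`/`(-+)` (visible from one) or `(--)`
#' (hidden from both). Content of `(+-)` points is transported from the
#' seeing place to the blind one with the morphisms [morphism_H1()] (site
#' translation) and [morphism_H2()] (feature map); `(++)` transports are
#' compared with the directly stored vectors to confirm the precision of
#' the map; `(--)` points cannot be filled by any pair. Coverage (fraction
#' of scene points with an occupied site) is reported per place before and
#' after filling.
#'
#' @param bundle A [place_bundle()].
#' @return An object of class `fill_report`: list with `pairs` (per-pair
#'   classification counts and `(++)` mean relative transport error),
#'   `coverage` (per place: before, after), and the filled memories.
#' @export
fill_occlusions <- function(bundle) {
  stopifnot(inherits(bundle, "place_bundle"))
  vis <- visibility_matrix(bundle)
  n_places <- length(bundle$places)
  pts <- bundle$scene$points
  coords <- as.matrix(pts[, c("x", "y", "z")])
  before <- vapply(seq_len(n_places), function(j) {
    mean(vapply(seq_len(nrow(pts)), function(i) {
      !is.null(gm_retrieve(bundle$memories[[j]],
                           coords[i, ] - bundle$places[[j]]))
    }, logical(1)))
  }, numeric(1))
  filled <- lapply(bundle$memories, gm_clone)  # keep the input bundle intact
  pair_rows <- list()
  for (i in seq_len(n_places)) for (j in seq_len(n_places)) {
    if (i == j) next
    cls <- c(pp = 0L, pm = 0L, mp = 0L, mm = 0L)
    errs <- c()
    for (k in seq_len(nrow(pts))) {
      vi <- vis[k, i]; vj <- vis[k, j]
      lab <- if (vi && vj) "pp" else if (vi && !vj) "pm" else if (!vi && vj) "mp" else "mm"
      cls[lab] <- cls[lab] + 1L
      if (!vi) next
      xi <- coords[k, ] - bundle$places[[i]]
      rec <- gm_retrieve(filled[[i]], xi)
      if (is.null(rec)) next
      qj <- morphism_H1(rec$q, bundle$places[[i]], bundle$places[[j]])
      h2 <- morphism_H2(rec$q$r, qj$r, dim = bundle$scene$dim)
      sl <- as.numeric(h2 %*% rec$sigma_l)
      sr <- as.numeric(h2 %*% rec$sigma_r)
      target <- gm_retrieve(filled[[j]], qj)
      if (vj && !is.null(target)) {
        denom <- sqrt(sum(target$sigma_l^2))
        if (denom > 0) {
          errs <- c(errs, sqrt(sum((sl - target$sigma_l)^2)) / denom)
        }
      } else if (is.null(target)) {
        filled[[j]] <- gm_store(filled[[j]], qj, sl, sr)
      }
    }
    pair_rows[[length(pair_rows) + 1L]] <-
      tibble::tibble(place_from = i, place_to = j,
                     n_pp = cls[["pp"]], n_pm = cls[["pm"]],
                     n_mp = cls[["mp"]], n_mm = cls[["mm"]],
                     mean_rel_err = if (length(errs)) mean(errs) else NA_real_)
  }
  after <- vapply(seq_len(n_places), function(j) {
    mean(vapply(seq_len(nrow(pts)), function(i) {
      !is.null(gm_retrieve(filled[[j]], coords[i, ] - bundle$places[[j]]))
    }, logical(1)))
  }, numeric(1))
  structure(list(pairs = dplyr::bind_rows(pair_rows),
                 coverage = tibble::tibble(place = seq_len(n_places),
                                           before = before, after = after),
                 memories = filled,
                 visibility = vis),
            class = "fill_report")
}

#' @export
print.fill_report <- function(x, ...) {
  cat("<fill report>\n")
  print(x$coverage)
  invisible(x)
}
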