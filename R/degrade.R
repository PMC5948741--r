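# Reconstruction-like degradation of ideal plant geometry.
#
# MVS dense clouds of small plants show three characteristic defects that the
# trait pipeline must survive: surface noise, ghost points offset from the
# true surface, and loss of fine end-details (leaf tips), the latter worst in
# thin-leaved monocots. The operators here emulate exactly those defects with
# seeded, reproducible draws.

#' Degradation specification
#'
#' Parameters controlling how an ideal mesh is degraded into a
#' reconstruction-like point cloud.
#'
#' @param point_density surface sampling density, points per cm^2.
#' @param noise_sigma_cm isotropic Gaussian displacement applied to surface
#'   samples, cm.
#' @param outlier_rate fraction of samples replaced by ghost points displaced
#'   2-10 cm off the surface along the local face normal (random sign).
#' @param tip_dropout_fraction mean fraction of each leaf's area removed
#'   starting from the tip (loss of end-details).
#' @param tip_dropout_jitter spread of the per-leaf removed fraction: each
#'   leaf loses `U(f*(1-j), f*(1+j))` of its area with `f =
#'   tip_dropout_fraction`, `j = tip_dropout_jitter`. `0` removes exactly `f`
#'   from every leaf; the default `1` models tip loss varying with leaf
#'   orientation and overlap, which is what degrades per-plant area recovery.
#' @param seed integer seed.
#' @return A `degradation_spec` list.
#' @export
degradation_spec <- function(point_density = 50, noise_sigma_cm = 0,
                             outlier_rate = 0, tip_dropout_fraction = 0,
                             tip_dropout_jitter = 1, seed = 1L) {
  check_scalar_number(point_density, "point_density", positive = TRUE)
  check_scalar_number(noise_sigma_cm, "noise_sigma_cm", nonneg = TRUE)
  check_scalar_number(outlier_rate, "outlier_rate", nonneg = TRUE)
  check_scalar_number(tip_dropout_fraction, "tip_dropout_fraction", nonneg = TRUE)
  check_scalar_number(tip_dropout_jitter, "tip_dropout_jitter", nonneg = TRUE)
  if (outlier_rate > 1) stop_param("`outlier_rate` must lie in [0, 1].")
  if (tip_dropout_fraction > 1) {
    stop_param("`tip_dropout_fraction` must lie in [0, 1].")
  }
  if (tip_dropout_jitter > 1) {
    stop_param("`tip_dropout_jitter` must lie in [0, 1].")
  }
  structure(
    list(
      point_density = point_density, noise_sigma_cm = noise_sigma_cm,
      outlier_rate = outlier_rate,
      tip_dropout_fraction = tip_dropout_fraction,
      tip_dropout_jitter = tip_dropout_jitter, seed = as.integer(seed)
    ),
    class = "degradation_spec"
  )
}

# Area-weighted uniform surface samples; returns positions plus the face id
# and interpolated vertex metadata for each sample.
sample_on_mesh <- function(mesh, n) {
  areas <- face_areas(mesh)
  fidx <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = areas)
  r1 <- sqrt(runif(n))
  r2 <- runif(n)
  w0 <- 1 - r1
  w1 <- r1 * (1 - r2)
  w2 <- r1 * r2
  f <- mesh$faces[fidx, , drop = FALSE]
  v <- mesh$vertices
  pts <- w0 * v[f[, 1], , drop = FALSE] + w1 * v[f[, 2], , drop = FALSE] +
    w2 * v[f[, 3], , drop = FALSE]
  u <- comp <- NULL
  if (!is.null(mesh$vertex_u)) {
    uu <- mesh$vertex_u
    u <- w0 * uu[f[, 1]] + w1 * uu[f[, 2]] + w2 * uu[f[, 3]]
  }
  if (!is.null(mesh$vertex_component)) {
    comp <- mesh$vertex_component[f[, 1]]
  }
  # face normals for the sampled faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-300)
  list(points = pts, u = u, component = comp, normals = nrm)
}

#' Sample a reconstruction-like point cloud from a plant mesh
#'
#' Draws area-weighted uniform surface samples at `spec$point_density`, then
#' applies, in order: leaf-tip dropout (removal of samples beyond the
#' axis position where the distal `tip_dropout_fraction` of each leaf's area
#' begins), ghost-point replacement (`outlier_rate` of the samples displaced
#' 2-10 cm off-surface along the local face normal with random sign), and
#' isotropic Gaussian noise of `noise_sigma_cm` on the remaining surface
#' samples. Deterministic for a fixed `spec$seed`.
#'
#' @param x a `plant_model` or a [triangle_mesh()]. Tip dropout needs the
#'   per-vertex leaf metadata carried by generated plants; on a bare mesh it
#'   is skipped with a warning.
#' @param spec a [degradation_spec()].
#' @return A [point_cloud()] tibble (`x`, `y`, `z`, `component`, `u`,
#'   `is_outlier`, `r`, `g`, `b`) in cm.
#' @export
sample_point_cloud <- function(x, spec = degradation_spec()) {
  mesh <- if (inherits(x, "plant_model")) x$mesh else x
  morphotype <- if (inherits(x, "plant_model")) x$morphotype else NULL
  if (!is_triangle_mesh(mesh)) stop_input("`x` must be a plant_model or triangle_mesh.")
  if (nrow(mesh$faces) == 0L) stop_input("Cannot sample an empty mesh.")
  if (!inherits(spec, "degradation_spec")) {
    stop_param("`spec` must be a degradation_spec().")
  }
  total_area <- sum(face_areas(mesh))
  n <- max(1L, round(spec$point_density * total_area))
  with_seed_(spec$seed, {
    s <- sample_on_mesh(mesh, n)
    keep <- rep(TRUE, n)
    if (spec$tip_dropout_fraction > 0) {
      if (is.null(s$u) || is.null(s$component) || is.null(morphotype)) {
        warn("Tip dropout requires generator leaf metadata; skipped.")
      } else {
        leaves <- sort(unique(s$component[s$component > 0L]))
        f0 <- spec$tip_dropout_fraction
        j <- spec$tip_dropout_jitter
        fracs <- runif(length(leaves), f0 * (1 - j), min(f0 * (1 + j), 1))
        for (li in seq_along(leaves)) {
          u_star <- leaf_tip_threshold(fracs[li], morphotype)
          keep[s$component == leaves[li] & !is.na(s$u) & s$u > u_star] <- FALSE
        }
      }
    }
    pts <- s$points[keep, , drop = FALSE]
    nrm <- s$normals[keep, , drop = FALSE]
    comp <- if (!is.null(s$component)) s$component[keep] else rep(NA_integer_, nrow(pts))
    u <- if (!is.null(s$u)) s$u[keep] else rep(NA_real_, nrow(pts))
    m <- nrow(pts)
    n_out <- round(spec$outlier_rate * m)
    is_out <- rep(FALSE, m)
    if (n_out > 0) {
      oi <- sample.int(m, n_out)
      is_out[oi] <- TRUE
      mag <- runif(n_out, 2, 10) * sample(c(-1, 1), n_out, replace = TRUE)
      pts[oi, ] <- pts[oi, , drop = FALSE] + mag * nrm[oi, , drop = FALSE]
    }
    if (spec$noise_sigma_cm > 0) {
      surf <- which(!is_out)
      pts[surf, ] <- pts[surf, , drop = FALSE] +
        matrix(rnorm(3 * length(surf), 0, spec$noise_sigma_cm), ncol = 3)
    }
    is_stem <- !is.na(comp) & comp == 0L
    rgb <- matrix(rep(c(60L, 150L, 55L), each = m), m, 3)   # leaf green
    if (any(is_stem)) {
      rgb[is_stem, ] <- rep(c(110L, 85L, 50L), each = sum(is_stem))  # stem brown
    }
    point_cloud(pts, rgb = rgb, unit_state = "cm",
                component = comp, u = u, is_outlier = is_out)
  })
}

#' Degrade a plant mesh into a reconstruction-like mesh
#'
#' Emulates the mesh an SfM-MVS workflow would deliver for a plant: each
#' leaf loses a (seeded, per-leaf variable) fraction of its distal area --
#' tips and thin end-details are the first casualties of dense
#' reconstruction -- and the whole surface is warped by a smooth
#' low-frequency displacement field standing in for reconstruction bias.
#' The warp is area-gentle (it tilts, it does not roughen), so triangle-sum
#' areas stay close to truth; the tip loss is what biases leaf area low.
#'
#' @param model a `plant_model`.
#' @param tip_dropout_fraction,tip_dropout_jitter see [degradation_spec()].
#' @param warp_amplitude_cm amplitude of the smooth displacement field, cm.
#' @param warp_wavelength_cm wavelength of the displacement field, cm.
#' @param seed integer seed.
#' @return A [triangle_mesh()] with attribute `leaf_area_retained_cm2`, the
#'   exact analytic area remaining per leaf after tip removal.
#' @export
degrade_mesh <- function(model, tip_dropout_fraction = 0,
                         tip_dropout_jitter = 1, warp_amplitude_cm = 0.05,
                         warp_wavelength_cm = 5, seed = 1L) {
  if (!inherits(model, "plant_model")) stop_input("`model` must be a plant_model.")
  check_scalar_number(tip_dropout_fraction, "tip_dropout_fraction", nonneg = TRUE)
  check_scalar_number(warp_amplitude_cm, "warp_amplitude_cm", nonneg = TRUE)
  check_scalar_number(warp_wavelength_cm, "warp_wavelength_cm", positive = TRUE)
  p <- model$params
  n_leaves <- length(model$per_leaf_areas_cm2)
  with_seed_(seed, {
    f0 <- tip_dropout_fraction
    j <- tip_dropout_jitter
    fracs <- if (f0 > 0) {
      runif(n_leaves, f0 * (1 - j), min(f0 * (1 + j), 1))
    } else {
      rep(0, n_leaves)
    }
    t_max <- vapply(fracs, function(f) leaf_tip_threshold(f, model$morphotype),
                    numeric(1))
    leaves <- vector("list", n_leaves)
    retained <- numeric(n_leaves)
    for (i in seq_len(n_leaves)) {
      if (model$morphotype == "dicot") {
        lf <- dicot_leaf_mesh(p$leaf_length_cm[i], p$leaf_width_cm[i],
                              p$fold_rad[i], p$n_u, p$n_v, t_max[i])
        rot <- rotation_about_axis(c(0, 0, 1), p$azimuth_rad[i]) %*%
          rotation_about_axis(c(0, 1, 0), -p$inclination_rad[i])
      } else {
        lf <- monocot_leaf_mesh(p$leaf_length_cm[i], p$leaf_width_cm,
                                p$theta0_rad[i], p$bend_rad[i],
                                p$n_s, p$n_v, t_max[i])
        rot <- rotation_about_axis(c(0, 0, 1), p$azimuth_rad[i])
      }
      origin <- c(p$stem_radius_cm * cos(p$azimuth_rad[i]),
                  p$stem_radius_cm * sin(p$azimuth_rad[i]),
                  p$insertion_frac[i] * model$truth_height_cm)
      lf <- transform_mesh(lf, rotation = rot, translation = origin)
      lf$vertex_component <- rep(i, nrow(lf$vertices))
      leaves[[i]] <- lf
      retained[i] <- model$per_leaf_areas_cm2[i] *
        (1 - leaf_tip_area_fraction(t_max[i], model$morphotype))
    }
    stem <- stem_mesh(model$truth_height_cm, p$stem_radius_cm)
    stem$vertex_component <- rep(0L, nrow(stem$vertices))
    stem$vertex_u <- rep(NA_real_, nrow(stem$vertices))
    mesh <- merge_meshes(c(list(stem), leaves))
    if (warp_amplitude_cm > 0) {
      v <- mesh$vertices
      ph <- runif(6, 0, 2 * pi)
      k <- 2 * pi / warp_wavelength_cm
      disp <- cbind(
        sin(k * v[, 2] + ph[1]) * cos(k * v[, 3] + ph[2]),
        sin(k * v[, 3] + ph[3]) * cos(k * v[, 1] + ph[4]),
        sin(k * v[, 1] + ph[5]) * cos(k * v[, 2] + ph[6])
      )
      mesh$vertices <- v + warp_amplitude_cm * disp
    }
    attr(mesh, "leaf_area_retained_cm2") <- retained
    attr(mesh, "tip_fractions") <- fracs
    mesh
  })
}
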