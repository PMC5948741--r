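# Parametric synthetic plants with exactly known traits.
#
# Both morphotypes are built from surfaces whose one-sided area has a closed
# form, so every generated plant carries analytic ground truth:
#  * dicot leaves are flat ovate sheets (half-width profile
#    w(t) = (W/2) * 6.75 t (1-t)^2, t = position along the midrib) folded
#    about a straight midrib -- the fold is an isometry, so one-sided area is
#    exactly 0.5625 * L * W;
#  * monocot leaves are ruled straps over a sagging circular arc with rulings
#    perpendicular to the bending plane and width profile W * (1-t)^0.7 --
#    the ruling direction is orthogonal to the unit-speed axis, so area is
#    exactly W * S / 1.7.
# The stem is an open tube; its lateral (mesh) area is recorded separately so
# leaf area can be isolated from a whole-plant triangle sum.

DICOT_PROFILE_INT <- 0.5625   # integral of 6.75 t (1-t)^2 over [0,1]
MONO_PROFILE_POW <- 0.7
MONO_PROFILE_INT <- 1 / (1 + MONO_PROFILE_POW)

dicot_halfwidth <- function(t) 6.75 * t * (1 - t)^2

# Fraction of a leaf's area lying beyond axis position t (toward the tip).
leaf_tip_area_fraction <- function(t, morphotype) {
  if (morphotype == "dicot") {
    ccdf <- function(u) {
      (6.75 * (u^2 / 2 - 2 * u^3 / 3 + u^4 / 4))
    }
    (DICOT_PROFILE_INT - ccdf(t)) / DICOT_PROFILE_INT
  } else {
    (1 - t)^(1 + MONO_PROFILE_POW)
  }
}

# Axis position beyond which `fraction` of the leaf's area lies.
leaf_tip_threshold <- function(fraction, morphotype) {
  if (fraction <= 0) return(1)
  if (fraction >= 1) return(0)
  if (morphotype == "monocot") {
    1 - fraction^(1 / (1 + MONO_PROFILE_POW))
  } else {
    stats::uniroot(
      function(t) leaf_tip_area_fraction(t, "dicot") - fraction,
      c(0, 1), tol = 1e-12
    )$root
  }
}

# --- leaf meshes ------------------------------------------------------------

# Shared strip/fan tessellator. `rows` is a list with one 3-column matrix of
# vertices per cross-section row (equal length f across rows), `row_u` the
# axis position per row. Optional apex points close the base and/or tip with
# triangle fans. Returns triangle_mesh with vertex_u metadata.
strip_mesh <- function(rows, row_u, nf, base_apex = NULL, tip_apex = NULL,
                       base_u = 0, tip_u = 1) {
  verts <- do.call(rbind, rows)
  u <- rep(row_u, each = nf)
  n_rows <- length(rows)
  faces <- list()
  for (i in seq_len(n_rows - 1L)) {
    a <- (i - 1L) * nf + seq_len(nf - 1L)
    b <- a + 1L
    c_ <- a + nf
    d <- b + nf
    faces[[length(faces) + 1L]] <- rbind(cbind(a, b, d), cbind(a, d, c_))
  }
  if (!is.null(base_apex)) {
    bi <- nrow(verts) + 1L
    verts <- rbind(verts, base_apex)
    u <- c(u, base_u)
    a <- seq_len(nf - 1L)
    faces[[length(faces) + 1L]] <- cbind(bi, a + 1L, a)
  }
  if (!is.null(tip_apex)) {
    ti <- nrow(verts) + 1L
    verts <- rbind(verts, tip_apex)
    u <- c(u, tip_u)
    a <- (n_rows - 1L) * nf + seq_len(nf - 1L)
    faces[[length(faces) + 1L]] <- cbind(ti, a, a + 1L)
  }
  triangle_mesh(verts, do.call(rbind, faces), vertex_u = u)
}

# Flat folded ovate sheet in a local frame: midrib along +x, base at origin.
# `t_max < 1` truncates the leaf at that axis position (open cut edge), used
# to model reconstruction tip loss with an exact analytic retained area.
dicot_leaf_mesh <- function(length_cm, width_cm, fold_rad, n_u, n_v,
                            t_max = 1) {
  tt <- seq(0, t_max, length.out = n_u + 1L)
  full <- t_max >= 1 - 1e-12
  t_rows <- if (full) tt[-c(1L, n_u + 1L)] else tt[-1L]
  f <- seq(-1, 1, length.out = 2L * n_v + 1L)
  hw <- (width_cm / 2) * dicot_halfwidth(t_rows)
  # rows of the folded sheet: y = f*hw*cos(fold), z = |f|*hw*sin(fold)
  rows <- lapply(seq_along(t_rows), function(i) {
    cbind(t_rows[i] * length_cm, f * hw[i] * cos(fold_rad),
          abs(f) * hw[i] * sin(fold_rad))
  })
  strip_mesh(rows, t_rows, length(f),
             base_apex = c(0, 0, 0),
             tip_apex = if (full) c(length_cm, 0, 0) else NULL)
}

# Ruled strap over a circular arc in the local x-z plane; rulings along y.
# Unit-speed axis: angle theta(s) = theta0 - kappa*s.
monocot_leaf_mesh <- function(length_cm, width_cm, theta0_rad, bend_rad,
                              n_s, n_v, t_max = 1) {
  kappa <- bend_rad / length_cm
  axis_pt <- function(t) {
    s <- t * length_cm
    if (abs(kappa) < 1e-12) {
      cbind(s * cos(theta0_rad), 0, s * sin(theta0_rad))
    } else {
      th <- theta0_rad - kappa * s
      cbind((sin(theta0_rad) - sin(th)) / kappa, 0,
            (cos(th) - cos(theta0_rad)) / kappa)
    }
  }
  tt <- seq(0, t_max, length.out = n_s + 1L)
  full <- t_max >= 1 - 1e-12
  t_rows <- if (full) tt[-(n_s + 1L)] else tt
  f <- seq(-1, 1, length.out = 2L * n_v + 1L)
  hw <- (width_cm / 2) * (1 - t_rows)^MONO_PROFILE_POW
  ax <- axis_pt(t_rows)
  rows <- lapply(seq_along(t_rows), function(i) {
    cbind(ax[i, 1], f * hw[i], ax[i, 3])
  })
  strip_mesh(rows, t_rows, length(f),
             tip_apex = if (full) axis_pt(1) else NULL)
}

# Open vertical stem tube, base ring centred at the origin.
stem_mesh <- function(height_cm, radius_cm, n_around = 24L, segs_per_cm = 4) {
  n_z <- max(6L, ceiling(height_cm * segs_per_cm))
  ang <- seq(0, 2 * pi, length.out = n_around + 1L)[-(n_around + 1L)]
  zs <- seq(0, height_cm, length.out = n_z + 1L)
  verts <- cbind(
    radius_cm * rep(cos(ang), times = n_z + 1L),
    radius_cm * rep(sin(ang), times = n_z + 1L),
    rep(zs, each = n_around)
  )
  faces <- vector("list", n_z)
  for (i in seq_len(n_z)) {
    a <- (i - 1L) * n_around + seq_len(n_around)
    b <- c(a[-1L], a[1L])
    c_ <- a + n_around
    d <- b + n_around
    faces[[i]] <- rbind(cbind(a, b, d), cbind(a, d, c_))
  }
  triangle_mesh(verts, do.call(rbind, faces))
}

# --- plant assembly ---------------------------------------------------------

new_plant_model <- function(morphotype, mesh, truth_height_cm,
                            per_leaf_areas_cm2, stem_area_cm2, params, seed) {
  structure(
    list(
      morphotype = morphotype,
      mesh = mesh,
      truth_height_cm = truth_height_cm,
      truth_leaf_area_cm2 = sum(per_leaf_areas_cm2),
      per_leaf_areas_cm2 = per_leaf_areas_cm2,
      stem_area_cm2 = stem_area_cm2,
      params = params,
      seed = as.integer(seed)
    ),
    class = "plant_model"
  )
}

#' @export
print.plant_model <- function(x, ...) {
  cat(sprintf(
    "<plant_model %s: height %.2f cm, leaf area %.2f cm^2 (%d leaves), seed %d>\n",
    x$morphotype, x$truth_height_cm, x$truth_leaf_area_cm2,
    length(x$per_leaf_areas_cm2), x$seed
  ))
  invisible(x)
}

assemble_plant <- function(morphotype, stem, leaves, placements,
                           height_cm, per_leaf_areas, params, seed) {
  stem$vertex_component <- rep(0L, nrow(stem$vertices))
  stem$vertex_u <- rep(NA_real_, nrow(stem$vertices))
  placed <- vector("list", length(leaves))
  for (i in seq_along(leaves)) {
    p <- placements[[i]]
    lf <- transform_mesh(leaves[[i]], rotation = p$rotation,
                         translation = p$origin)
    lf$vertex_component <- rep(i, nrow(lf$vertices))
    placed[[i]] <- lf
  }
  mesh <- merge_meshes(c(list(stem), placed))
  stem_faces <- mesh$vertex_component[mesh$faces[, 1]] == 0L
  stem_area <- sum(face_areas(mesh)[stem_faces])
  new_plant_model(morphotype, mesh, height_cm, per_leaf_areas, stem_area,
                  params, seed)
}

#' Generate a synthetic dicot plant
#'
#' Builds a broad-leaved (dicot) plant: a vertical stem tube of exactly
#' `height_cm` with ovate folded leaf sheets inserted along it
#' (golden-angle phyllotaxis with seeded jitter, an apical stem segment left
#' bare as in young weeds). Leaf sizes taper toward the apex. Every leaf is a
#' flat folded sheet, so its one-sided area has the closed form
#' `0.5625 * length * width`; the returned model records exact per-leaf areas,
#' their sum, and the stem's lateral mesh area.
#'
#' @param height_cm stem base-to-tip length, cm (the trait recovered by the
#'   height pipeline). The generator targets the 4-30 cm range typical of
#'   young field weeds.
#' @param n_leaves number of leaves (>= 1).
#' @param leaf_scale basal leaf length as a fraction of plant height
#'   (default 0.75, giving leaf-area-to-height regimes comparable to small
#'   broad-leaved weeds, e.g. roughly 100 cm^2 at 12 cm height with 6 leaves).
#' @param seed integer seed; identical seeds give bit-identical plants.
#' @param n_u,n_v leaf tessellation density along/across the midrib.
#' @param stem_radius_cm stem tube radius, cm.
#' @return A `plant_model`: mesh (cm, z-up, stem base at the origin), exact
#'   `truth_height_cm`, `truth_leaf_area_cm2`, `per_leaf_areas_cm2`,
#'   `stem_area_cm2`, generator parameters and seed.
#' @export
generate_dicot <- function(height_cm, n_leaves = 6L, leaf_scale = 0.75,
                           seed = 1L, n_u = 96L, n_v = 6L,
                           stem_radius_cm = 0.15) {
  check_scalar_number(height_cm, "height_cm", positive = TRUE)
  n_leaves <- check_count(n_leaves, "n_leaves", min = 1L)
  check_scalar_number(leaf_scale, "leaf_scale", positive = TRUE)
  with_seed_(seed, {
    idx <- seq_len(n_leaves)
    taper <- 1 - 0.4 * (idx - 1) / max(n_leaves - 1, 1)
    len <- leaf_scale * height_cm * taper * runif(n_leaves, 0.92, 1.08)
    wid <- 0.6 * len
    fold <- (20 + runif(n_leaves, -5, 5)) * pi / 180
    incl <- (30 + runif(n_leaves, -8, 8)) * pi / 180
    azim <- (137.50776 * (idx - 1) + runif(n_leaves, -10, 10)) * pi / 180
    ins_frac <- seq(0.25, 0.80, length.out = n_leaves) +
      runif(n_leaves, -0.02, 0.02)
    ins_frac <- pmin(pmax(ins_frac, 0.05), 0.82)
    leaves <- lapply(idx, function(i) {
      dicot_leaf_mesh(len[i], wid[i], fold[i], n_u, n_v)
    })
    placements <- lapply(idx, function(i) {
      rot <- rotation_about_axis(c(0, 0, 1), azim[i]) %*%
        rotation_about_axis(c(0, 1, 0), -incl[i])
      origin <- c(stem_radius_cm * cos(azim[i]),
                  stem_radius_cm * sin(azim[i]),
                  ins_frac[i] * height_cm)
      list(rotation = rot, origin = origin)
    })
    per_leaf <- DICOT_PROFILE_INT * len * wid
    stem <- stem_mesh(height_cm, stem_radius_cm)
    params <- list(
      height_cm = height_cm, n_leaves = n_leaves, leaf_scale = leaf_scale,
      stem_radius_cm = stem_radius_cm, n_u = n_u, n_v = n_v,
      leaf_length_cm = len, leaf_width_cm = wid,
      fold_rad = fold, inclination_rad = incl, azimuth_rad = azim,
      insertion_frac = ins_frac
    )
    assemble_plant("dicot", stem, leaves, placements, height_cm, per_leaf,
                   params, seed)
  })
}

#' Generate a synthetic monocot plant
#'
#' Builds a grass-like (monocot) plant: a vertical stem with elongated,
#' tapered strap leaves that arch outward over a sagging circular arc
#' (distichous insertion with seeded jitter). Each strap is a ruled surface
#' whose rulings are orthogonal to the unit-speed leaf axis, so its one-sided
#' area has the closed form `width * length / 1.7`. The thin, curved leaves
#' are what makes this morphotype harder to reconstruct and to measure.
#'
#' @inheritParams generate_dicot
#' @param leaf_length_ratio basal leaf length as a fraction of plant height
#'   (default 0.8).
#' @param leaf_width_cm leaf width at the base, cm. Every leaf must satisfy a
#'   length:width aspect ratio of at least `min_aspect`.
#' @param min_aspect minimum allowed length:width ratio (default 10).
#' @param n_s,n_v strap tessellation density along/across the axis.
#' @return A `plant_model` (see [generate_dicot()]).
#' @export
generate_monocot <- function(height_cm, n_leaves = 5L, leaf_length_ratio = 0.8,
                             leaf_width_cm = 1.0, seed = 1L, min_aspect = 10,
                             n_s = 120L, n_v = 2L, stem_radius_cm = 0.15) {
  check_scalar_number(height_cm, "height_cm", positive = TRUE)
  n_leaves <- check_count(n_leaves, "n_leaves", min = 1L)
  check_scalar_number(leaf_length_ratio, "leaf_length_ratio", positive = TRUE)
  check_scalar_number(leaf_width_cm, "leaf_width_cm", positive = TRUE)
  base_len <- leaf_length_ratio * height_cm
  min_len <- base_len * 0.7 * 0.92
  if (min_len / leaf_width_cm < min_aspect) {
    stop_param(sprintf(
      "Monocot leaves must be at least %g:1 long:wide; shortest leaf %.2f cm vs width %.2f cm.",
      min_aspect, min_len, leaf_width_cm
    ))
  }
  with_seed_(seed, {
    idx <- seq_len(n_leaves)
    taper <- 1 - 0.3 * (idx - 1) / max(n_leaves - 1, 1)
    len <- base_len * taper * runif(n_leaves, 0.92, 1.08)
    theta0 <- (55 + runif(n_leaves, -10, 10)) * pi / 180
    bend <- (70 + runif(n_leaves, -20, 20)) * pi / 180
    azim <- (180 * (idx - 1) + runif(n_leaves, -25, 25)) * pi / 180
    ins_frac <- seq(0.30, 0.95, length.out = n_leaves) +
      runif(n_leaves, -0.02, 0.02)
    ins_frac <- pmin(pmax(ins_frac, 0.05), 0.97)
    leaves <- lapply(idx, function(i) {
      monocot_leaf_mesh(len[i], leaf_width_cm, theta0[i], bend[i], n_s, n_v)
    })
    placements <- lapply(idx, function(i) {
      rot <- rotation_about_axis(c(0, 0, 1), azim[i])
      origin <- c(stem_radius_cm * cos(azim[i]),
                  stem_radius_cm * sin(azim[i]),
                  ins_frac[i] * height_cm)
      list(rotation = rot, origin = origin)
    })
    per_leaf <- MONO_PROFILE_INT * len * leaf_width_cm
    stem <- stem_mesh(height_cm, stem_radius_cm)
    params <- list(
      height_cm = height_cm, n_leaves = n_leaves,
      leaf_length_ratio = leaf_length_ratio, leaf_width_cm = leaf_width_cm,
      stem_radius_cm = stem_radius_cm, n_s = n_s, n_v = n_v,
      leaf_length_cm = len, theta0_rad = theta0, bend_rad = bend,
      azimuth_rad = azim, insertion_frac = ins_frac
    )
    assemble_plant("monocot", stem, leaves, placements, height_cm, per_leaf,
                   params, seed)
  })
}
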