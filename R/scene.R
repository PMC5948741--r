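# Scene assembly: embed a plant cloud in a ground patch with three graphic
# scale markers and optional neighbouring plants, then export everything in
# arbitrary ("uncalibrated") units so the calibration stage has real work to
# do. In the field protocol the three 10 cm scales lie on the ground in a
# triangle around the target plant.

#' Default triangular marker layout
#'
#' Three 10 cm markers lying flat on the ground plane, tangentially oriented
#' at equal angles around the plant axis.
#'
#' @param radius_cm distance of marker centres from the plant axis.
#' @param true_length_cm physical marker length (default 10 cm).
#' @return A tibble with columns `marker_id`, `ax..az`, `bx..bz`,
#'   `true_length_cm` (coordinates in cm).
#' @export
marker_layout <- function(radius_cm = 12, true_length_cm = 10) {
  ang <- c(90, 210, 330) * pi / 180
  half <- true_length_cm / 2
  tibble(
    marker_id = paste0("m", 1:3),
    ax = radius_cm * cos(ang) - half * sin(ang),
    ay = radius_cm * sin(ang) + half * cos(ang),
    az = 0,
    bx = radius_cm * cos(ang) + half * sin(ang),
    by = radius_cm * sin(ang) - half * cos(ang),
    bz = 0,
    true_length_cm = true_length_cm
  )
}

#' Assemble an uncalibrated scene around a plant cloud
#'
#' Adds a ground patch at `z = 0`, three scale markers, and optional
#' neighbouring plant clouds, then divides every coordinate by `scale_factor`
#' so the exported scene is in arbitrary model units whose true cm-per-unit
#' equals `scale_factor` -- exactly what an SfM reconstruction looks like
#' before the graphic scales are used to calibrate it. Neighbour clouds are
#' rotated, jittered copies of the plant placed so that all their points lie
#' beyond `exclusion_radius_cm` from the plant axis; the shared ground patch
#' keeps the scene connected, which is why bounding-box cleaning (not
#' filtering) is what separates plants.
#'
#' @param plant_cloud a calibrated (cm) [point_cloud()].
#' @param markers marker tibble as from [marker_layout()] (cm).
#' @param scale_factor true cm per scene unit; must be positive.
#' @param n_neighbors number of neighbouring plants.
#' @param seed integer seed.
#' @param ground_radius_cm radius of the circular ground patch.
#' @param ground_density_cm2 ground sampling density, points per cm^2.
#' @param ground_sigma_cm Gaussian z-noise on ground points (0 = exact plane).
#' @param exclusion_radius_cm neighbours keep all points beyond this
#'   horizontal distance from the plant axis.
#' @return A `scene`: list with `plant`, `ground`, `neighbors` (list),
#'   `markers` (tibble, scene units), `true_scale`.
#' @export
build_scene <- function(plant_cloud, markers = marker_layout(),
                        scale_factor = 1, n_neighbors = 0L, seed = 1L,
                        ground_radius_cm = 16, ground_density_cm2 = 25,
                        ground_sigma_cm = 0, exclusion_radius_cm = 8) {
  check_scalar_number(scale_factor, "scale_factor", positive = TRUE)
  n_neighbors <- check_count(n_neighbors, "n_neighbors", min = 0L)
  if (nrow(markers) < 1L) stop_param("At least one marker is required.")
  s <- 1 / scale_factor
  with_seed_(seed, {
    n_g <- max(3L, round(ground_density_cm2 * pi * ground_radius_cm^2))
    rr <- ground_radius_cm * sqrt(runif(n_g))
    th <- runif(n_g, 0, 2 * pi)
    gz <- if (ground_sigma_cm > 0) rnorm(n_g, 0, ground_sigma_cm) else rep(0, n_g)
    ground <- point_cloud(cbind(rr * cos(th), rr * sin(th), gz),
                          rgb = matrix(rep(c(120L, 100L, 80L), each = n_g), ncol = 3),
                          unit_state = "cm")
    neighbors <- list()
    if (n_neighbors > 0) {
      pxy <- cloud_xyz(plant_cloud)
      span <- max(sqrt(pxy[, 1]^2 + pxy[, 2]^2))
      for (i in seq_len(n_neighbors)) {
        rot <- rotation_about_axis(c(0, 0, 1), runif(1, 0, 2 * pi))
        d <- exclusion_radius_cm + span + runif(1, 0.5, 2)
        az <- runif(1, 0, 2 * pi)
        xyz <- pxy %*% t(rot)
        xyz[, 1] <- xyz[, 1] + d * cos(az)
        xyz[, 2] <- xyz[, 2] + d * sin(az)
        nb <- plant_cloud
        nb$x <- xyz[, 1]; nb$y <- xyz[, 2]; nb$z <- xyz[, 3]
        neighbors[[i]] <- as_point_cloud(nb, unit_state = "cm")
      }
    }
    scale_coords <- function(cl) {
      cl$x <- cl$x * s; cl$y <- cl$y * s; cl$z <- cl$z * s
      as_point_cloud(cl, unit_state = "uncalibrated")
    }
    mk <- markers
    for (col in c("ax", "ay", "az", "bx", "by", "bz")) mk[[col]] <- mk[[col]] * s
    structure(
      list(
        plant = scale_coords(plant_cloud),
        ground = scale_coords(ground),
        neighbors = lapply(neighbors, scale_coords),
        markers = mk,
        true_scale = scale_factor
      ),
      class = "scene"
    )
  })
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf(
    "<scene: %d plant + %d ground points, %d neighbors, %d markers, true scale %g cm/unit>\n",
    nrow(x$plant), nrow(x$ground), length(x$neighbors), nrow(x$markers),
    x$true_scale
  ))
  invisible(x)
}

#' Merge a scene into one labelled point cloud
#'
#' Binds plant, ground and neighbour points into a single uncalibrated cloud
#' with a `source` column (`"plant"`, `"ground"`, `"neighbor<i>"`), the form
#' in which an SfM export would arrive.
#'
#' @param scene a [build_scene()] result.
#' @return A [point_cloud()] tibble.
#' @export
scene_cloud <- function(scene) {
  if (!inherits(scene, "scene")) stop_input("`scene` must be a scene.")
  parts <- c(
    list(dplyr::mutate(tibble::as_tibble(scene$plant), source = "plant"),
         dplyr::mutate(tibble::as_tibble(scene$ground), source = "ground")),
    purrr::imap(scene$neighbors, function(nb, i) {
      dplyr::mutate(tibble::as_tibble(nb), source = paste0("neighbor", i))
    })
  )
  out <- dplyr::bind_rows(parts)
  as_point_cloud(out, unit_state = unit_state(scene$plant))
}
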