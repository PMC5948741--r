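# End-to-end pipeline: simulate study data, process scenes into trait
# records, and validate traits against ground truth. Everything is driven by
# one flat config so a run is reproducible from (config, seed) alone; every
# output directory gets a provenance block (config hash, package version,
# seed) and identical configs produce byte-identical outputs.

#' Pipeline configuration
#'
#' Flat key-value configuration with validated ranges. The simulation block
#' mirrors a field study of young weeds: three species groups (two
#' broad-leaved dicots of different stature and one monocot), ten plants per
#' group, heights in the 4-30 cm range, reconstruction-like degradation
#' (sigma = 0.1 cm surface noise, 2% ghost points, monocot tip loss).
#'
#' @param ... overrides of the defaults listed below.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_per_species = 10L,
    # synthetic study conditions
    point_density = 50,
    ground_density = 25,
    noise_sigma_cm = 0.1,
    outlier_rate = 0.02,
    tip_dropout_dicot = 0,
    tip_dropout_monocot = 0.05,
    scale_min = 0.5,
    scale_max = 2,
    n_neighbors = 0L,
    # processing parameters
    filter_k = 12L,
    filter_std_ratio = 2.0,
    grid_max_dist_cm = 0.5,
    crop_min = c(-25, -25, -1),
    crop_max = c(25, 25, 40),
    ransac_inlier_cm = 0.2,
    ransac_trials = 200L,
    stem_radius_cm = 1.0,
    # imaging parameters
    coeffs_preset = "ga2018",
    px_per_cm = 20,
    square_area_cm2 = 100,
    # logging
    verbose = TRUE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop_param(paste0("Unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  cfg$seed <- check_count(cfg$seed, "seed")
  cfg$n_per_species <- check_count(cfg$n_per_species, "n_per_species")
  cfg$n_neighbors <- check_count(cfg$n_neighbors, "n_neighbors")
  check_scalar_number(cfg$point_density, "point_density", positive = TRUE)
  check_scalar_number(cfg$noise_sigma_cm, "noise_sigma_cm", nonneg = TRUE)
  if (cfg$outlier_rate < 0 || cfg$outlier_rate > 1) {
    stop_param("`outlier_rate` must lie in [0, 1].")
  }
  if (cfg$scale_min <= 0 || cfg$scale_max < cfg$scale_min) {
    stop_param("Scale range must satisfy 0 < scale_min <= scale_max.")
  }
  check_scalar_number(cfg$stem_radius_cm, "stem_radius_cm", positive = TRUE)
  if (!cfg$coeffs_preset %in% c("ga2018", "exg")) {
    stop_param("`coeffs_preset` must be 'ga2018' or 'exg'.")
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline config file (YAML)
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a [pipeline_config()];
#'   `write_pipeline_config()` the path, invisibly.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) rlang::hash(unclass(config))

write_provenance <- function(config, out_dir) {
  jsonlite::write_json(
    list(
      config_hash = config_hash(config),
      package_version = as.character(utils::packageVersion("phenocloud")),
      seed = config$seed
    ),
    file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
}

log_stage <- function(verbose, stage, n_in, n_out) {
  if (verbose) {
    inform(sprintf("[%s] in=%d out=%d removed=%d", stage, n_in, n_out,
                   n_in - n_out))
  }
}

species_table <- function() {
  tibble(
    species = c("dicot_broad", "dicot_small", "monocot"),
    morphotype = c("dicot", "dicot", "monocot"),
    height_min = c(8, 4, 10),
    height_max = c(18, 11, 30)
  )
}

#' Simulate a synthetic study
#'
#' Emits `n_per_species` plants for each of three species groups (two dicots
#' of contrasting stature, one monocot): per plant a ground-truth mesh, a
#' degraded "reconstructed" mesh, an uncalibrated scene cloud (ground patch,
#' three 10 cm markers, optional neighbours), a marker CSV, a detached-leaf
#' layout PNG, and one row in `truth.csv`. Fully seeded: the same config
#' yields byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the truth tibble.
#' @export
pipeline_simulate <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_io(sprintf("Cannot create '%s'.", out_dir))
  sp <- species_table()
  rows <- list()
  for (si in seq_len(nrow(sp))) {
    for (i in seq_len(config$n_per_species)) {
      seed_i <- derive_seed(config$seed, si * 1000L + i)
      plant_id <- sprintf("%s_%02d", sp$species[si], i)
      height <- with_seed_(seed_i, runif(1, sp$height_min[si], sp$height_max[si]))
      model <- if (sp$morphotype[si] == "dicot") {
        n_leaves <- with_seed_(derive_seed(seed_i, 2L), sample(5:7, 1))
        generate_dicot(height, n_leaves = n_leaves, seed = derive_seed(seed_i, 3L))
      } else {
        n_leaves <- with_seed_(derive_seed(seed_i, 2L), sample(4:6, 1))
        generate_monocot(height, n_leaves = n_leaves,
                         leaf_width_cm = 0.05 * height,
                         seed = derive_seed(seed_i, 3L))
      }
      tip_f <- if (model$morphotype == "dicot") config$tip_dropout_dicot else
        config$tip_dropout_monocot
      spec <- degradation_spec(
        point_density = config$point_density,
        noise_sigma_cm = config$noise_sigma_cm,
        outlier_rate = config$outlier_rate,
        tip_dropout_fraction = tip_f,
        seed = derive_seed(seed_i, 4L)
      )
      cloud <- sample_point_cloud(model, spec)
      recon <- degrade_mesh(model, tip_dropout_fraction = tip_f,
                            seed = derive_seed(seed_i, 5L))
      scale_f <- with_seed_(derive_seed(seed_i, 6L),
                            runif(1, config$scale_min, config$scale_max))
      scene <- build_scene(
        cloud, scale_factor = scale_f, n_neighbors = config$n_neighbors,
        seed = derive_seed(seed_i, 7L),
        ground_density_cm2 = config$ground_density,
        ground_sigma_cm = config$noise_sigma_cm
      )
      recon_scene <- recon
      recon_scene$vertices <- recon_scene$vertices / scale_f
      recon_scene$unit_state <- "uncalibrated"
      layout <- render_leaf_layout(model, px_per_cm = config$px_per_cm,
                                   square_area_cm2 = config$square_area_cm2,
                                   seed = derive_seed(seed_i, 8L))
      write_ply(model$mesh, file.path(out_dir, paste0(plant_id, "_truth_mesh.ply")))
      write_ply(recon_scene, file.path(out_dir, paste0(plant_id, "_recon_mesh.ply")))
      write_ply(scene_cloud(scene), file.path(out_dir, paste0(plant_id, "_scene.ply")))
      readr::write_csv(scene$markers,
                       file.path(out_dir, paste0(plant_id, "_markers.csv")))
      write_rgb_image(layout, file.path(out_dir, paste0(plant_id, "_layout.png")))
      rows[[length(rows) + 1L]] <- tibble(
        plant_id = plant_id,
        species = sp$species[si],
        morphotype = model$morphotype,
        truth_height_cm = model$truth_height_cm,
        truth_leaf_area_cm2 = model$truth_leaf_area_cm2,
        stem_area_cm2 = model$stem_area_cm2,
        truth_total_area_cm2 = model$truth_leaf_area_cm2 + model$stem_area_cm2,
        true_scale = scale_f,
        layout_plant_px = attr(layout, "plant_px"),
        seed = seed_i
      )
      if (config$verbose) inform(sprintf("simulated %s (h = %.1f cm)", plant_id, height))
    }
  }
  truth <- if (length(rows) > 0) dplyr::bind_rows(rows) else tibble(
    plant_id = character(), species = character(), morphotype = character(),
    truth_height_cm = numeric(), truth_leaf_area_cm2 = numeric(),
    stem_area_cm2 = numeric(), truth_total_area_cm2 = numeric(),
    true_scale = numeric(), layout_plant_px = integer(), seed = integer()
  )
  readr::write_csv(truth, file.path(out_dir, "truth.csv"))
  write_provenance(config, out_dir)
  invisible(truth)
}

#' Process one scene into a trait record
#'
#' The cleaning-and-measurement chain for a single plant: statistical outlier
#' removal, metric calibration from the marker CSV, the 0.5 cm grid-distance
#' filter, bounding-box cropping, robust ground-plane fit, and trait
#' extraction (cylindrical-stem height; triangle-sum area of the calibrated
#' reconstructed mesh). Calibration runs before the grid filter because that
#' filter's threshold is metric.
#'
#' @param scene_ply path to the uncalibrated scene cloud (PLY).
#' @param markers_csv path to the marker endpoint CSV.
#' @param recon_mesh_ply optional path to the reconstructed mesh (PLY, scene
#'   units); without it leaf area is 0.
#' @param config a [pipeline_config()].
#' @param plant_id identifier for the output row.
#' @return A one-row trait tibble (see [extract_traits()]) plus stage counts
#'   in the attribute `stage_log`.
#' @export
process_scene <- function(scene_ply, markers_csv, recon_mesh_ply = NULL,
                          config = pipeline_config(), plant_id = "plant") {
  if (!file.exists(markers_csv)) {
    stop_io(sprintf("Marker CSV '%s' not found; cannot calibrate.", markers_csv))
  }
  cloud <- read_ply(scene_ply, unit_state = "uncalibrated")
  log <- list()
  n0 <- nrow(cloud)
  cloud <- remove_statistical_outliers(cloud, k = config$filter_k,
                                       std_ratio = config$filter_std_ratio)
  log$statistical_filter <- c(n_in = n0, n_out = nrow(cloud))
  log_stage(config$verbose, "statistical_filter", n0, nrow(cloud))

  markers <- readr::read_csv(markers_csv, show_col_types = FALSE)
  est <- calibrate_scale(markers)
  cloud <- apply_scale(cloud, est)
  log$calibrate <- c(n_in = nrow(cloud), n_out = nrow(cloud))
  if (config$verbose) {
    inform(sprintf("[calibrate] cm_per_unit=%.6g residual=%.3g%%",
                   est$cm_per_unit, est$residual_pct))
  }

  n1 <- nrow(cloud)
  cloud <- grid_distance_filter(cloud, max_dist_cm = config$grid_max_dist_cm,
                                k = config$filter_k)
  log$grid_filter <- c(n_in = n1, n_out = nrow(cloud))
  log_stage(config$verbose, "grid_filter", n1, nrow(cloud))

  n2 <- nrow(cloud)
  cloud <- crop_bounding_box(cloud, config$crop_min, config$crop_max)
  log$crop <- c(n_in = n2, n_out = nrow(cloud))
  log_stage(config$verbose, "crop", n2, nrow(cloud))

  ground <- fit_ground_plane(cloud, inlier_dist_cm = config$ransac_inlier_cm,
                             n_trials = config$ransac_trials,
                             seed = derive_seed(config$seed, 97L))
  mesh <- NULL
  if (!is.null(recon_mesh_ply)) {
    mesh <- read_ply(recon_mesh_ply, unit_state = "uncalibrated")
    mesh <- apply_scale(mesh, est)
  }
  traits <- extract_traits(cloud, mesh, ground, config = list(
    plant_id = plant_id, stem_radius_cm = config$stem_radius_cm
  ))
  traits$cm_per_unit <- est$cm_per_unit
  attr(traits, "stage_log") <- log
  traits
}

#' Process all scenes in a simulation directory
#'
#' Discovers `<id>_scene.ply` files and runs [process_scene()] on each,
#' writing `traits.csv` and a provenance block. Errors in one scene abort the
#' run unless `keep_going = TRUE`, in which case they are logged and skipped.
#'
#' @param in_dir directory produced by [pipeline_simulate()].
#' @param out_dir output directory for `traits.csv`.
#' @param config a [pipeline_config()].
#' @param keep_going continue past per-scene errors (default FALSE).
#' @return The trait tibble, invisibly.
#' @export
pipeline_process <- function(in_dir, out_dir = in_dir,
                             config = pipeline_config(), keep_going = FALSE) {
  scenes <- sort(list.files(in_dir, pattern = "_scene\\.ply$", full.names = TRUE))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (sc in scenes) {
    id <- sub("_scene\\.ply$", "", basename(sc))
    mk <- file.path(in_dir, paste0(id, "_markers.csv"))
    rm_ <- file.path(in_dir, paste0(id, "_recon_mesh.ply"))
    if (!file.exists(rm_)) rm_ <- NULL
    res <- tryCatch(
      process_scene(sc, mk, rm_, config = config, plant_id = id),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      if (!keep_going) {
        abort(sprintf("Processing failed for '%s': %s", id,
                      conditionMessage(res)), parent = res)
      }
      warn(sprintf("Skipping '%s': %s", id, conditionMessage(res)))
      next
    }
    rows[[length(rows) + 1L]] <- res
  }
  traits <- if (length(rows) > 0) dplyr::bind_rows(rows) else tibble(
    plant_id = character(), est_height_cm = numeric(),
    est_height_max_extent_cm = numeric(), est_leaf_area_cm2 = numeric(),
    method_flags = character(), cm_per_unit = numeric()
  )
  readr::write_csv(traits, file.path(out_dir, "traits.csv"))
  write_provenance(config, out_dir)
  invisible(traits)
}

#' Validate estimated traits against ground truth
#'
#' Joins truth and trait tables by `plant_id` (order-independent) and writes
#' per-morphotype and pooled validation reports for plant height and plant
#' surface area. The mesh triangle-sum includes the stem tube, so it is
#' compared against `truth_total_area_cm2` (leaves + stem), mirroring a field
#' protocol in which detached stems are imaged together with the leaves.
#'
#' @param truth either the truth tibble or a path to `truth.csv`.
#' @param traits either the trait tibble or a path to `traits.csv`.
#' @param out_dir optional directory for report JSON/CSV files.
#' @param plots also write scatter plots (PNG) for each report.
#' @return A tibble of tidied reports (one row per trait x group).
#' @export
pipeline_validate <- function(truth, traits, out_dir = NULL, plots = FALSE) {
  if (is.character(truth)) truth <- readr::read_csv(truth, show_col_types = FALSE)
  if (is.character(traits)) traits <- readr::read_csv(traits, show_col_types = FALSE)
  orphans_t <- setdiff(truth$plant_id, traits$plant_id)
  orphans_e <- setdiff(traits$plant_id, truth$plant_id)
  if (length(orphans_t) > 0L || length(orphans_e) > 0L) {
    stop_input(sprintf(
      "plant_id mismatch between truth and traits. Missing traits: [%s]; missing truth: [%s].",
      paste(orphans_t, collapse = ", "), paste(orphans_e, collapse = ", ")
    ))
  }
  joined <- dplyr::inner_join(truth, traits, by = "plant_id")
  groups <- c("pooled", sort(unique(joined$morphotype)))
  out <- list()
  for (g in groups) {
    dat <- if (g == "pooled") joined else dplyr::filter(joined, morphotype == g)
    if (nrow(dat) < 2L) next
    rep_h <- validation_report(dat, truth_height_cm, est_height_cm,
                               label = plant_id,
                               trait = paste0("height_", g))
    rep_a <- validation_report(dat, truth_total_area_cm2, est_leaf_area_cm2,
                               label = plant_id,
                               trait = paste0("leaf_area_", g))
    out[[paste0("height_", g)]] <- rep_h
    out[[paste0("leaf_area_", g)]] <- rep_a
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_validation_json(rep_h, file.path(out_dir, sprintf("validation_height_%s.json", g)))
      write_validation_json(rep_a, file.path(out_dir, sprintf("validation_leaf_area_%s.json", g)))
      if (plots) {
        ggplot2::ggsave(
          file.path(out_dir, sprintf("scatter_height_%s.png", g)),
          autoplot(rep_h), width = 5, height = 4, dpi = 120
        )
        ggplot2::ggsave(
          file.path(out_dir, sprintf("scatter_leaf_area_%s.png", g)),
          autoplot(rep_a), width = 5, height = 4, dpi = 120
        )
      }
    }
  }
  summary <- dplyr::bind_rows(lapply(out, tidy))
  if (!is.null(out_dir)) {
    readr::write_csv(summary, file.path(out_dir, "validation_summary.csv"))
  }
  summary
}

#' Image-based leaf areas for a directory of layout images
#'
#' Runs [leaf_area_from_image()] on every `<id>_layout.png` and writes
#' `image_leaf_area.csv`.
#'
#' @param in_dir directory containing layout PNGs.
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return Tibble of per-plant image leaf areas, invisibly.
#' @export
pipeline_image_la <- function(in_dir, out_dir = in_dir,
                              config = pipeline_config()) {
  files <- sort(list.files(in_dir, pattern = "_layout\\.png$", full.names = TRUE))
  co <- coeffs_preset(config$coeffs_preset)
  rows <- lapply(files, function(f) {
    id <- sub("_layout\\.png$", "", basename(f))
    area <- leaf_area_from_image(read_rgb_image(f), coeffs = co,
                                 square_area_cm2 = config$square_area_cm2)
    tibble(plant_id = id, image_leaf_area_cm2 = as.numeric(area),
           px_per_cm2 = attr(area, "px_per_cm2"))
  })
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else tibble(
    plant_id = character(), image_leaf_area_cm2 = numeric(),
    px_per_cm2 = numeric()
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(out, file.path(out_dir, "image_leaf_area.csv"))
  invisible(out)
}

#' Run the full pipeline
#'
#' `simulate -> process -> image-la -> validate` in one call.
#'
#' @param config a [pipeline_config()].
#' @param out_dir working directory for all artefacts.
#' @return The validation summary tibble.
#' @export
pipeline_run <- function(config = pipeline_config(), out_dir) {
  pipeline_simulate(config, out_dir)
  pipeline_process(out_dir, out_dir, config)
  pipeline_image_la(out_dir, out_dir, config)
  pipeline_validate(file.path(out_dir, "truth.csv"),
                    file.path(out_dir, "traits.csv"),
                    out_dir = out_dir)
}
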